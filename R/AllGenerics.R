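#' Number of frames in a dataset
#' @param x an [EnsembleDataset-class]
#' @return integer
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of atoms in a dataset
#' @param x an [EnsembleDataset-class]
#' @return integer
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Coordinate array of a dataset
#' @param x an [EnsembleDataset-class]
#' @return frames x atoms x 3 array (nm)
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Atom metadata table
#' @param x an [EnsembleDataset-class]
#' @return data.frame with resid, resname, name
#' @export
setGeneric("atomInfo", function(x) standardGeneric("atomInfo"))

#' Per-frame variant ids
#' @param x an [EnsembleDataset-class]
#' @return factor of length frames
#' @export
setGeneric("variantOf", function(x) standardGeneric("variantOf"))

#' Per-variant binary class labels
#' @param x an [EnsembleDataset-class]
#' @return named integer vector
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' Reference coordinates
#' @param x an [EnsembleDataset-class]
#' @return atoms x 3 matrix (nm)
#' @export
setGeneric("referenceCoords", function(x) standardGeneric("referenceCoords"))

#' Encode raw coordinates to the latent space
#' @param object a [DiffNet-class]
#' @param x frames x 3N coordinate matrix (nm, dataset atom order) or an
#'   [EnsembleDataset-class]
#' @return frames x latent matrix
#' @export
setGeneric("encode", function(object, x) standardGeneric("encode"))

#' Decode latent vectors back to coordinates
#' @param object a [DiffNet-class]
#' @param z frames x latent matrix
#' @return frames x 3N coordinate matrix (nm, dataset atom order)
#' @export
setGeneric("decode", function(object, z) standardGeneric("decode"))

#' Classification-head output for latent vectors
#' @param object a [DiffNet-class]
#' @param z frames x latent matrix
#' @return numeric vector in (0, 1)
#' @export
setGeneric("classifyLatent", function(object, z) standardGeneric("classifyLatent"))

#' Full forward pass: reconstruction, latent and classifier output
#' @param object a [DiffNet-class]
#' @param x frames x 3N coordinate matrix (nm) or an [EnsembleDataset-class]
#' @return list with `reconstruction`, `latent`, `yhat`
#' @export
setGeneric("forwardPass", function(object, x) standardGeneric("forwardPass"))
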