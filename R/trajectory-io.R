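# Trajectory and array I/O. PDB and DCD reading go through bio3d; a DCD
# writer is provided here (CHARMM-style Fortran records, little-endian)
# because no installed reader/writer pair exists for writing, and the writer
# is round-trip verified against bio3d::read.dcd.

#' Write coordinates to a DCD trajectory file
#'
#' Writes a CHARMM-format binary DCD (little-endian, no unit cell). The
#' coordinate units are whatever is passed in; MD convention for DCD is
#' Angstroms, and [writeEnsembleFiles()] converts from the package-internal
#' nm before calling this.
#'
#' @param coords frames x atoms x 3 numeric array.
#' @param path output file.
#' @return invisibly, `path`
#' @export
writeDcd <- function(coords, path) {
  stopUnless(length(dim(coords)) == 3L && dim(coords)[3] == 3L,
             "coords must be a frames x atoms x 3 array")
  nframes <- dim(coords)[1]
  natoms <- dim(coords)[2]
  con <- file(path, "wb")
  on.exit(close(con))
  wInt <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  # header record: "CORD" + 20 control integers
  wInt(84L)
  writeChar("CORD", con, nchars = 4L, eos = NULL)
  icntrl <- integer(20)
  icntrl[1] <- nframes
  icntrl[2] <- 1L   # first step
  icntrl[3] <- 1L   # save interval
  icntrl[4] <- nframes
  icntrl[20] <- 24L # CHARMM version flag
  wInt(icntrl)
  wInt(84L)
  # title record
  title <- sprintf("%-80s", "Synthetic ensemble written by DiffNetR")
  wInt(4L + 80L)
  wInt(1L)
  writeChar(title, con, nchars = 80L, eos = NULL)
  wInt(4L + 80L)
  # atom-count record
  wInt(4L)
  wInt(natoms)
  wInt(4L)
  recLen <- 4L * natoms
  for (f in seq_len(nframes)) {
    for (k in 1:3) {
      wInt(recLen)
      writeBin(as.numeric(coords[f, , k]), con, size = 4L, endian = "little")
      wInt(recLen)
    }
  }
  invisible(path)
}

# Reference/topology PDB for a dataset (coordinates converted nm -> Angstrom).
writeReferencePdb <- function(dataset, path) {
  at <- atomInfo(dataset)
  xyz <- as.vector(t(referenceCoords(dataset) * 10))
  bio3d::write.pdb(
    file = path,
    xyz = xyz,
    resno = at$resid,
    resid = at$resname,
    elety = at$name,
    chain = rep("A", nrow(at))
  )
  invisible(path)
}

#' Load trajectories into an EnsembleDataset
#'
#' Reads a PDB topology/reference and one or more DCD trajectories, retains
#' only backbone atoms without carbonyl oxygens (C, CA, CB, N; glycine
#' contributes three atoms since it has no CB), concatenates frames with
#' their variant provenance, and converts Angstroms to the package-internal
#' nm. Frames are not aligned here; see [alignToReference()].
#'
#' @param topology path to a PDB file; its coordinates become the reference.
#' @param trajectories named character vector of DCD paths; names are the
#'   variant ids.
#' @param classTable data.frame with columns `variant` and `class` (0/1), or
#'   the path of a delimited text file with those columns.
#' @param stride keep every `stride`-th frame (default 1: keep all; MD-scale
#'   inputs conventionally use 10).
#' @return an [EnsembleDataset-class]
#' @export
loadEnsemble <- function(topology, trajectories, classTable, stride = 1L) {
  stopUnless(length(trajectories) > 0, "at least one trajectory is required")
  stopUnless(!is.null(names(trajectories)) && all(nzchar(names(trajectories))),
             "trajectories must be named by variant id")
  if (is.character(classTable)) {
    classTable <- read.table(classTable, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  }
  stopUnless(all(c("variant", "class") %in% names(classTable)),
             "class table needs columns 'variant' and 'class'")
  missing <- setdiff(names(trajectories), classTable$variant)
  if (length(missing) > 0)
    stop("unknown variant in class table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  stopUnless(all(classTable$class %in% c(0, 1)), "classes must be 0 or 1")

  pdb <- bio3d::read.pdb(topology)
  keep <- which(pdb$atom$elety %in% c("C", "CA", "CB", "N") &
                pdb$atom$type %in% c("ATOM", "HETATM"))
  stopUnless(length(keep) > 0, "topology contains no backbone C/CA/CB/N atoms")
  nTopoAtoms <- nrow(pdb$atom)
  atoms <- data.frame(
    resid = pdb$atom$resno[keep],
    resname = pdb$atom$resid[keep],
    name = pdb$atom$elety[keep],
    stringsAsFactors = FALSE
  )
  refFull <- matrix(pdb$xyz, ncol = 3, byrow = TRUE)
  reference <- refFull[keep, , drop = FALSE] / 10

  blocks <- list()
  variantPerFrame <- character(0)
  for (v in names(trajectories)) {
    before <- getAllConnections()
    xyz <- tryCatch(
      suppressWarnings(bio3d::read.dcd(trajectories[[v]], verbose = FALSE)),
      error = function(e) {
        # the reader can leave its file connection open on failure
        for (co in setdiff(getAllConnections(), before)) {
          try(close(getConnection(co)), silent = TRUE)
        }
        stop("failed to read DCD '", trajectories[[v]], "': ",
             conditionMessage(e), call. = FALSE)
      }
    )
    if (is.null(dim(xyz)) || nrow(xyz) == 0)
      stop("trajectory '", trajectories[[v]], "' contains no frames", call. = FALSE)
    if (ncol(xyz) != 3L * nTopoAtoms)
      stop("atom-count mismatch: trajectory '", trajectories[[v]], "' has ",
           ncol(xyz) / 3, " atoms but the topology has ", nTopoAtoms, call. = FALSE)
    rows <- seq(1L, nrow(xyz), by = as.integer(stride))
    blocks[[v]] <- xyz[rows, coordIdx(keep), drop = FALSE] / 10
    variantPerFrame <- c(variantPerFrame, rep(v, length(rows)))
  }
  flat <- do.call(rbind, blocks)
  classes <- setNames(as.integer(classTable$class), classTable$variant)
  classes <- classes[names(trajectories)]
  new("EnsembleDataset",
    coords = unflattenCoords(flat, nrow(atoms)),
    atoms = atoms,
    variant = factor(variantPerFrame, levels = names(trajectories)),
    classLabels = classes,
    reference = reference
  )
}

#' Save a numeric matrix as a NumPy .npy file
#'
#' Minimal NPY v1.0 writer (little-endian float64, C order), used to export
#' whitened feature matrices and transform components in a format that
#' downstream numeric tooling reads natively.
#'
#' @param mat numeric matrix or vector.
#' @param path output file.
#' @return invisibly, `path`
#' @export
saveNpy <- function(mat, path) {
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  shape <- paste0("(", nrow(mat), ", ", ncol(mat), ")")
  dict <- paste0("{'descr': '<f8', 'fortran_order': False, 'shape': ", shape, ", }")
  # total header (magic 8 + len 2 + dict) padded to a multiple of 64, ends \n
  unpadded <- 10L + nchar(dict) + 1L
  pad <- (64L - unpadded %% 64L) %% 64L
  dict <- paste0(dict, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(dict)), con, size = 2L, endian = "little")
  writeChar(dict, con, nchars = nchar(dict), eos = NULL)
  writeBin(as.numeric(t(mat)), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a .npy file written by [saveNpy()] (or NumPy, float64 2-D)
#' @param path file path
#' @return numeric matrix
#' @export
loadNpy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 8L)
  stopUnless(identical(magic[1:6], as.raw(c(0x93, charToRaw("NUMPY")))),
             "not an NPY file")
  hlen <- readBin(con, "integer", n = 1L, size = 2L, endian = "little", signed = FALSE)
  header <- readChar(con, nchars = hlen, useBytes = TRUE)
  stopUnless(grepl("'<f8'", header, fixed = TRUE), "only float64 NPY is supported")
  stopUnless(grepl("False", header, fixed = TRUE), "only C-order NPY is supported")
  m <- regmatches(header, regexec("\\(([0-9]+),\\s*([0-9]+)\\)", header))[[1]]
  stopUnless(length(m) == 3L, "could not parse NPY shape")
  r <- as.integer(m[2]); cc <- as.integer(m[3])
  vals <- readBin(con, "numeric", n = r * cc, size = 8L, endian = "little")
  matrix(vals, nrow = r, byrow = TRUE)
}
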