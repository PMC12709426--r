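## Coordinate and trajectory I/O.
##
## GRO is parsed by fixed columns (cols 1-5 resid, 6-10 resname, 11-15 atom
## name, 16-20 atom number, then three 8-wide coordinate fields) so merged
## fields survive. PDB atom records go through bio3d; the box is taken from
## CRYST1. Internal unit is nm throughout; PDB Angstrom are converted on the
## way in and out. Only orthorhombic boxes are accepted.

.parseGroLine <- function(line, lineno) {
  if (nchar(line) < 44)
    .stopf("GRO format error at line %d: atom line truncated (%d chars, need >= 44)",
           lineno, nchar(line))
  x <- suppressWarnings(as.numeric(substr(line, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(line, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(line, 37, 44)))
  if (anyNA(c(x, y, z)))
    .stopf("GRO format error at line %d: non-numeric coordinate field", lineno)
  list(resid = suppressWarnings(as.integer(substr(line, 1, 5))),
       resname = trimws(substr(line, 6, 10)),
       atom = trimws(substr(line, 11, 15)),
       x = x, y = y, z = z)
}

.parseGroBox <- function(line, lineno) {
  v <- suppressWarnings(as.numeric(strsplit(trimws(line), "\\s+")[[1]]))
  if (length(v) < 3 || anyNA(v[1:3]))
    .stopf("GRO format error at line %d: malformed box line", lineno)
  if (length(v) > 3 && any(abs(v[4:length(v)]) > 1e-9))
    .stopf("GRO format error at line %d: triclinic box not supported", lineno)
  v[1:3]
}

.parseGroTime <- function(title) {
  m <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
  if (length(m)) as.numeric(sub("t=\\s*", "", m)) else NA_real_
}

## parse one GRO frame starting at lines[start]; returns frame + next index
.readGroFrame <- function(lines, start) {
  title <- lines[start]
  n <- suppressWarnings(as.integer(trimws(lines[start + 1])))
  if (is.na(n) || n < 1)
    .stopf("GRO format error at line %d: bad atom count", start + 1)
  if (start + 1 + n + 1 > length(lines))
    .stopf("GRO format error: file ends before %d atoms + box (frame at line %d)",
           n, start)
  idx <- (start + 2):(start + 1 + n)
  rec <- lapply(seq_along(idx), function(i) .parseGroLine(lines[idx[i]], idx[i]))
  box <- .parseGroBox(lines[start + 2 + n], start + 2 + n)
  pos <- cbind(vapply(rec, `[[`, 0, "x"), vapply(rec, `[[`, 0, "y"),
               vapply(rec, `[[`, 0, "z"))
  meta <- data.frame(
    moleculeId = vapply(rec, `[[`, 0L, "resid"),
    moleculeName = vapply(rec, `[[`, "", "resname"),
    beadName = vapply(rec, `[[`, "", "atom"),
    stringsAsFactors = FALSE)
  list(positions = pos, box = box, beadMeta = meta,
       time = .parseGroTime(title), nextLine = start + 3 + n)
}

#' Read a coarse-grained coordinate file
#'
#' Reads a single-frame GRO or PDB file into a [BeadFrame-class]. PDB
#' coordinates (Angstrom) are converted to nm; the box comes from the GRO
#' box line or the PDB CRYST1 record. Triclinic boxes are rejected.
#'
#' @param path file path.
#' @param format `"gro"`, `"pdb"` or `"auto"` (by extension).
#' @return a [BeadFrame-class].
#' @export
readCoordinates <- function(path, format = c("auto", "gro", "pdb")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "gro"
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (format == "gro") {
    lines <- readLines(path)
    fr <- .readGroFrame(lines, 1)
    t <- if (is.na(fr$time)) 0 else fr$time
    newBeadFrame(fr$positions, fr$box, fr$beadMeta, t)
  } else {
    lines <- readLines(path)
    cr <- grep("^CRYST1", lines, value = TRUE)
    if (!length(cr)) .stopf("PDB format error: missing CRYST1 box record")
    abc <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                        substr(cr[1], 25, 33)))
    ang <- as.numeric(c(substr(cr[1], 34, 40), substr(cr[1], 41, 47),
                        substr(cr[1], 48, 54)))
    if (anyNA(abc)) .stopf("PDB format error: malformed CRYST1 record")
    if (any(abs(ang - 90) > 1e-6))
      .stopf("PDB format error: triclinic box not supported (angles %s)",
             paste(ang, collapse = ", "))
    p <- bio3d::read.pdb(path, verbose = FALSE)
    a <- p$atom
    meta <- data.frame(moleculeId = as.integer(a$resno),
                       moleculeName = a$resid, beadName = a$elety,
                       stringsAsFactors = FALSE)
    newBeadFrame(cbind(a$x, a$y, a$z) / 10, abc / 10, meta, 0)
  }
}

.formatGroAtoms <- function(frame) {
  m <- frame@beadMeta
  p <- frame@positions
  sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
          m$moleculeId %% 100000, substr(m$moleculeName, 1, 5),
          substr(m$beadName, 1, 5), seq_len(nrow(p)) %% 100000,
          p[, 1], p[, 2], p[, 3])
}

#' Write a coordinate file
#'
#' @param frame a [BeadFrame-class].
#' @param path output path.
#' @param format `"gro"`, `"pdb"` or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
writeCoordinates <- function(frame, path, format = c("auto", "gro", "pdb")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "gro"
  if (format == "gro") {
    lines <- c(sprintf("memsense frame t= %.3f", frame@time),
               sprintf("%5d", nrow(frame@positions)),
               .formatGroAtoms(frame),
               sprintf("%10.5f%10.5f%10.5f", frame@box[1], frame@box[2],
                       frame@box[3]))
    writeLines(lines, path)
  } else {
    m <- frame@beadMeta
    p <- frame@positions * 10
    lines <- c(
      sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
              frame@box[1] * 10, frame@box[2] * 10, frame@box[3] * 10,
              90, 90, 90),
      sprintf("ATOM  %5d %-4s %-4s%5d    %8.3f%8.3f%8.3f  1.00  0.00",
              seq_len(nrow(p)) %% 100000, substr(m$beadName, 1, 4),
              substr(m$moleculeName, 1, 4), m$moleculeId %% 100000,
              p[, 1], p[, 2], p[, 3]),
      "END")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Write a trajectory
#'
#' Multi-frame GRO (concatenated frames, `t=` stamps in the title lines) or
#' binary TRR.
#'
#' @param trajectory a [Trajectory-class].
#' @param path output path.
#' @param format `"gro"`, `"trr"` or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(trajectory, path, format = c("auto", "gro", "trr")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.trr$", path, ignore.case = TRUE)) "trr" else "gro"
  if (format == "trr") return(writeTRR(trajectory, path))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nFrames(trajectory))) {
    fr <- getFrame(trajectory, i)
    writeLines(c(sprintf("memsense frame t= %.3f", fr@time),
                 sprintf("%5d", nrow(fr@positions)),
                 .formatGroAtoms(fr),
                 sprintf("%10.5f%10.5f%10.5f", fr@box[1], fr@box[2],
                         fr@box[3])), con)
  }
  invisible(path)
}

#' Count frames in a trajectory file without loading coordinates
#'
#' @param path trajectory path (multi-frame GRO or TRR).
#' @return integer frame count.
#' @export
countFrames <- function(path) {
  if (grepl("\\.trr$", path, ignore.case = TRUE)) {
    n <- 0L
    con <- file(path, "rb")
    on.exit(close(con))
    while (!is.null(.readTRRFrame(con, skipCoords = TRUE))) n <- n + 1L
    return(n)
  }
  lines <- readLines(path)
  n <- 0L; i <- 1L
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1])))
    if (is.na(nat)) .stopf("GRO format error at line %d: bad atom count", i + 1)
    n <- n + 1L
    i <- i + 3L + nat
  }
  n
}

#' Read a trajectory
#'
#' Reads a multi-frame GRO or binary TRR trajectory. A topology frame
#' (coordinate file) may be given to validate the bead count and supply
#' bead metadata for TRR files (which store none).
#'
#' @param path trajectory path.
#' @param topology optional [BeadFrame-class] or coordinate file path.
#' @param stride keep every `stride`-th frame (default 1).
#' @param format `"gro"`, `"trr"` or `"auto"`.
#' @return a [Trajectory-class].
#' @export
readTrajectory <- function(path, topology = NULL, stride = 1L,
                           format = c("auto", "gro", "trr")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.trr$", path, ignore.case = TRUE)) "trr" else "gro"
  if (is.character(topology)) topology <- readCoordinates(topology)
  stride <- as.integer(stride)
  stopifnot(stride >= 1)

  if (format == "trr") {
    frames <- readTRR(path)
    coords <- lapply(frames, `[[`, "x")
    boxes <- do.call(rbind, lapply(frames, `[[`, "box"))
    times <- vapply(frames, `[[`, 0, "time")
    if (is.null(topology))
      .stopf("TRR trajectories need a topology for bead metadata")
    meta <- topology@beadMeta
  } else {
    lines <- readLines(path)
    coords <- list(); boxes <- NULL; times <- NULL; meta <- NULL
    i <- 1L
    while (i <= length(lines)) {
      fr <- .readGroFrame(lines, i)
      coords[[length(coords) + 1L]] <- fr$positions
      boxes <- rbind(boxes, fr$box)
      times <- c(times, fr$time)
      if (is.null(meta)) meta <- fr$beadMeta
      else if (nrow(meta) != nrow(fr$beadMeta))
        .stopf("structural error: frame %d has %d beads, first frame has %d",
               length(coords), nrow(fr$beadMeta), nrow(meta))
      i <- fr$nextLine
    }
    if (anyNA(times)) times <- (seq_along(coords) - 1) * 400
  }
  if (!is.null(topology) && nrow(topology@beadMeta) != nrow(coords[[1]]))
    .stopf("structural error: topology has %d beads, trajectory frames have %d",
           nrow(topology@beadMeta), nrow(coords[[1]]))
  keep <- seq(1L, length(coords), by = stride)
  newTrajectory(coords[keep], boxes[keep, , drop = FALSE], times[keep], meta)
}

## ---- TRR (big-endian XDR, single precision, positions only) ---------------

.readTRRFrame <- function(con, skipCoords = FALSE) {
  magic <- readBin(con, "integer", 1, 4, endian = "big")
  if (length(magic) == 0) return(NULL)
  if (magic != 1993) .stopf("TRR format error: bad magic %d", magic)
  slen <- readBin(con, "integer", 1, 4, endian = "big")   # buffer len
  vlen <- readBin(con, "integer", 1, 4, endian = "big")   # string len
  readBin(con, "raw", ((vlen + 3) %/% 4) * 4)             # version string
  sizes <- readBin(con, "integer", 10, 4, endian = "big")
  names(sizes) <- c("ir", "e", "box", "vir", "pres", "top", "sym", "x", "v", "f")
  natoms <- readBin(con, "integer", 1, 4, endian = "big")
  step <- readBin(con, "integer", 1, 4, endian = "big")
  nre <- readBin(con, "integer", 1, 4, endian = "big")
  dbl <- sizes["box"] == 72 || sizes["x"] == natoms * 24
  fsz <- if (dbl) 8L else 4L
  time <- readBin(con, "double", 1, fsz, endian = "big")
  lambda <- readBin(con, "double", 1, fsz, endian = "big")
  box <- NULL
  if (sizes["box"] > 0) {
    bm <- matrix(readBin(con, "double", 9, fsz, endian = "big"), 3, byrow = TRUE)
    if (any(abs(bm[lower.tri(bm) | upper.tri(bm)]) > 1e-7))
      .stopf("TRR format error: triclinic box not supported")
    box <- diag(bm)
  }
  for (s in c("vir", "pres")) if (sizes[s] > 0)
    readBin(con, "raw", 9 * fsz)
  x <- NULL
  if (sizes["x"] > 0) {
    if (skipCoords) readBin(con, "raw", as.integer(3 * natoms * fsz))
    else x <- matrix(readBin(con, "double", 3 * natoms, fsz, endian = "big"),
                     ncol = 3, byrow = TRUE)
  }
  for (s in c("v", "f")) if (sizes[s] > 0)
    readBin(con, "raw", as.integer(3 * natoms * fsz))
  list(natoms = natoms, step = step, time = time, box = box, x = x)
}

#' Read a TRR trajectory file
#'
#' Minimal reader for the GROMACS TRR layout (big-endian XDR; positions and
#' box; single or double precision; orthorhombic boxes only).
#'
#' @param path TRR path.
#' @return list of frames, each with `natoms`, `step`, `time`, `box`
#'   (length-3, nm) and `x` (N x 3 matrix, nm).
#' @export
readTRR <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  frames <- list()
  repeat {
    fr <- .readTRRFrame(con)
    if (is.null(fr)) break
    frames[[length(frames) + 1L]] <- fr
  }
  if (!length(frames)) .stopf("TRR format error: empty file %s", path)
  frames
}

#' Write a TRR trajectory file
#'
#' @param trajectory a [Trajectory-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTRR <- function(trajectory, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  ver <- charToRaw("GMX_trn_file")
  n <- nrow(trajectory@beadMeta)
  for (i in seq_len(nFrames(trajectory))) {
    writeBin(1993L, con, 4, endian = "big")
    writeBin(13L, con, 4, endian = "big")
    writeBin(12L, con, 4, endian = "big")
    writeBin(ver, con)
    sizes <- c(0L, 0L, 36L, 0L, 0L, 0L, 0L, as.integer(n * 12), 0L, 0L)
    writeBin(sizes, con, 4, endian = "big")
    writeBin(as.integer(n), con, 4, endian = "big")
    writeBin(i - 1L, con, 4, endian = "big")
    writeBin(0L, con, 4, endian = "big")
    writeBin(as.numeric(trajectory@times[i]), con, 4, endian = "big")
    writeBin(0, con, 4, endian = "big")
    b <- trajectory@boxes[i, ]
    writeBin(as.numeric(c(b[1], 0, 0, 0, b[2], 0, 0, 0, b[3])), con, 4,
             endian = "big")
    writeBin(as.numeric(t(trajectory@coords[[i]])), con, 4, endian = "big")
  }
  invisible(path)
}

## ---- selections -----------------------------------------------------------

#' Define a bead selection
#'
#' Selections match on molecule name and/or bead name, with an optional
#' leaflet restriction resolved by [assignLeaflets()].
#'
#' @param name label for reports.
#' @param moleculeName character vector of molecule names to match, or NULL.
#' @param beadName character vector of bead names to match, or NULL.
#' @param leaflet `"both"` (default), `"upper"` or `"lower"`.
#' @return a `SelectionSpec` (list with class).
#' @export
beadSelection <- function(name, moleculeName = NULL, beadName = NULL,
                          leaflet = c("both", "upper", "lower")) {
  leaflet <- match.arg(leaflet)
  structure(list(name = name, moleculeName = moleculeName,
                 beadName = beadName, leaflet = leaflet),
            class = "SelectionSpec")
}

#' Resolve a selection on a frame
#'
#' Deterministic: returns the sorted bead indices matching the spec. A
#' leaflet restriction needs `leaflets`, the per-lipid labels from
#' [assignLeaflets()]. An empty result is legal and returned as an empty
#' integer vector.
#'
#' @param frame a [BeadFrame-class].
#' @param spec a `SelectionSpec` from [beadSelection()].
#' @param leaflets optional named character vector (moleculeId -> label).
#' @return sorted integer bead indices.
#' @export
selectBeads <- function(frame, spec, leaflets = NULL) {
  m <- frame@beadMeta
  keep <- rep(TRUE, nrow(m))
  if (!is.null(spec$moleculeName)) keep <- keep & m$moleculeName %in% spec$moleculeName
  if (!is.null(spec$beadName)) keep <- keep & m$beadName %in% spec$beadName
  if (spec$leaflet != "both") {
    if (is.null(leaflets))
      leaflets <- assignLeaflets(frame)
    keep <- keep & !is.na(leaflets[as.character(m$moleculeId)]) &
      leaflets[as.character(m$moleculeId)] == spec$leaflet
  }
  sort(which(keep))
}

## ---- configuration --------------------------------------------------------

#' Analysis configuration
#'
#' Collects the tunable parameters shared across stages, all with the
#' package defaults. Every value is echoed into run reports so that
#' parameters without a literature-fixed value stay visible.
#'
#' @param temperature simulation temperature, K.
#' @param cylinderRadius radius of the phosphate selection cylinder for
#'   insertion depth, nm.
#' @param fourierModes length-2 integer (Mx, My) Fourier truncation.
#' @param curvatureBreaks histogram bin edges for mean curvature, nm^-1.
#' @param defectGridStep packing-defect grid step, nm.
#' @param defectZDepth depth below the local phosphate level defining a
#'   deep defect, nm.
#' @param defectBeadRadius bead radius used in the grid scan, nm.
#' @param defectAMin lower area cutoff for the exponential tail fit, A^2.
#' @param tmZCut,tmTiltCut,adsZCut state-window parameters: transmembrane if
#'   `|cv1| <= tmZCut` and tilt (folded to `[0, 90]`) `<= tmTiltCut`;
#'   adsorbed beyond `|cv1| >= adsZCut`; inserted otherwise.
#' @param maskThreshold accessible-weight mask threshold for reweighting.
#' @param seed default RNG seed for generators.
#' @return an `AnalysisConfig` (list with class).
#' @export
analysisConfig <- function(temperature = 310,
                           cylinderRadius = 1.0,
                           fourierModes = c(3L, 3L),
                           curvatureBreaks = seq(-0.15, 0.15, by = 0.005),
                           defectGridStep = 0.1,
                           defectZDepth = 0.1,
                           defectBeadRadius = 0.26,
                           defectAMin = 15,
                           tmZCut = 0.5,
                           tmTiltCut = 45,
                           adsZCut = 1.2,
                           maskThreshold = 1e-4,
                           seed = 1L) {
  stopifnot(temperature > 0, cylinderRadius > 0, all(fourierModes >= 0),
            defectGridStep > 0, tmZCut < adsZCut)
  structure(list(temperature = temperature, cylinderRadius = cylinderRadius,
                 fourierModes = as.integer(fourierModes),
                 curvatureBreaks = curvatureBreaks,
                 defectGridStep = defectGridStep, defectZDepth = defectZDepth,
                 defectBeadRadius = defectBeadRadius, defectAMin = defectAMin,
                 tmZCut = tmZCut, tmTiltCut = tmTiltCut, adsZCut = adsZCut,
                 maskThreshold = maskThreshold, seed = as.integer(seed)),
            class = "AnalysisConfig")
}

#' Read an analysis configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the package defaults.
#'
#' @param path YAML file.
#' @return an `AnalysisConfig`.
#' @export
readConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysisConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad)) .stopf("unknown config keys: %s", paste(bad, collapse = ", "))
  do.call(analysisConfig, vals)
}

#' Write a result table with commented metadata header
#'
#' CSV with a header row, preceded by '#'-prefixed metadata lines.
#'
#' @param df data.frame.
#' @param path output path.
#' @param meta named list written as `# key: value` lines.
#' @return `path`, invisibly.
#' @export
writeResultTable <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(format(meta[[k]]), collapse = " ")), con)
  write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
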