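# Laccase sequence comparison: global alignment, percent identity, and
# Kyte-Doolittle hydropathy profiling with difference-region detection.

#' Kyte-Doolittle hydropathy scale
#' @format named numeric vector over the 20 standard residues; `X` maps to 0.
#' @export
kyte_doolittle <- c(
  I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
  G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
  H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5,
  X = 0
)

check_protein_alphabet <- function(s) {
  bad <- setdiff(strsplit(s, "")[[1]], names(kyte_doolittle))
  if (length(bad)) {
    stop("invalid residue(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  invisible(s)
}

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties via
#' `Biostrings::pairwiseAlignment`. Defaults (BLOSUM62, gap opening 10, gap
#' extension 0.5) follow common CLUSTALW-style protein parameters.
#'
#' @param a,b protein sequences (plain strings, standard one-letter alphabet
#'   plus X).
#' @param substitution_matrix name of a matrix shipped with Biostrings
#'   (default `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return an `aligned_pair`: character vector of the two gapped sequences
#'   with attributes `score`, `ids`.
#' @export
global_align <- function(a, b, substitution_matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  check_protein_alphabet(a); check_protein_alphabet(b)
  al <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global",
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  out <- c(as.character(Biostrings::alignedPattern(al)),
           as.character(Biostrings::alignedSubject(al)))
  attr(out, "score") <- Biostrings::score(al)
  class(out) <- "aligned_pair"
  out
}

#' Percent identity of an aligned pair
#'
#' Identities divided by the number of aligned columns containing at least
#' one residue (i.e. excluding all-gap columns), times 100. Alternative
#' denominators: `"ungapped"` (columns with residues in both sequences) and
#' `"shorter"` (length of the shorter unaligned sequence).
#'
#' @param aligned an `aligned_pair` from [global_align()], or any character
#'   vector of two equal-length gapped sequences.
#' @param mode identity denominator convention.
#' @return percent identity (0-100); the convention is recorded as attribute
#'   `mode`.
#' @export
percent_identity <- function(aligned,
                             mode = c("aligned_columns", "ungapped",
                                      "shorter")) {
  mode <- match.arg(mode)
  s1 <- strsplit(aligned[1], "")[[1]]
  s2 <- strsplit(aligned[2], "")[[1]]
  if (length(s1) != length(s2)) {
    stop("aligned sequences differ in length", call. = FALSE)
  }
  ident <- sum(s1 == s2 & s1 != "-")
  denom <- switch(mode,
    aligned_columns = sum(s1 != "-" | s2 != "-"),
    ungapped = sum(s1 != "-" & s2 != "-"),
    shorter = min(sum(s1 != "-"), sum(s2 != "-"))
  )
  out <- 100 * ident / denom
  attr(out, "mode") <- mode
  out
}

#' Kyte-Doolittle hydropathy profile
#'
#' Sliding unweighted mean of the Kyte-Doolittle residue values over windows
#' of the given length; position i of the profile covers residues
#' i..i+window-1.
#'
#' @param s protein sequence (string).
#' @param window window length (default 9).
#' @return tibble with `position` (window start) and `hydropathy`; attribute
#'   `window`.
#' @export
hydropathy_profile <- function(s, window = 9) {
  check_protein_alphabet(s)
  res <- strsplit(s, "")[[1]]
  if (window > length(res)) {
    stop("window longer than the sequence", call. = FALSE)
  }
  vals <- unname(kyte_doolittle[res])
  prof <- as.numeric(stats::filter(vals, rep(1 / window, window),
                                   sides = 1))
  prof <- prof[window:length(vals)]
  out <- tibble::tibble(position = seq_along(prof), hydropathy = prof)
  attr(out, "window") <- window
  out
}

#' Regions where two hydropathy profiles differ
#'
#' Maximal contiguous runs of positions where |p1 - p2| exceeds the
#' threshold. Runs separated by even a single sub-threshold position are
#' reported separately (no merging).
#'
#' @param p1,p2 profiles from [hydropathy_profile()] on a shared coordinate
#'   system (equal length).
#' @param threshold difference threshold (default 1.0 hydropathy units).
#' @return tibble of regions: `start`, `end` (inclusive positions),
#'   `max_abs_diff`.
#' @export
hydropathy_diff_regions <- function(p1, p2, threshold = 1.0) {
  if (nrow(p1) != nrow(p2)) {
    stop("profiles differ in length: align coordinates first", call. = FALSE)
  }
  d <- abs(p1$hydropathy - p2$hydropathy)
  over <- d > threshold
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  tibble::tibble(
    start = p1$position[starts[keep]],
    end = p1$position[ends[keep]],
    max_abs_diff = vapply(keep, function(k) {
      max(d[starts[k]:ends[k]])
    }, numeric(1))
  )
}

#' Read protein sequences from a FASTA file
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), sub(" .*", "", names(aa)))
}
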