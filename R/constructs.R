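# Synthetic validation constructs: "molecular clock" triggers with a given
# percentage of uniformly randomized positions (simulating neutral sequence
# divergence at ~2% per million years) and window constructs matching the
# target only over one block embedded in a fully randomized backbone.

#' Random RNA sequence
#'
#' @param len Length in nucleotides.
#' @param seed Optional integer seed (sets the RNG).
#' @return Single RNA string, uniform over A/C/G/U.
#' @export
random_rna <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

#' Generate a molecular-clock construct
#'
#' Randomizes `percent`% of the positions of `base`: `round(percent * len /
#' 100)` distinct positions are drawn uniformly without replacement and
#' each is assigned a base drawn uniformly from A/C/G/U — the original
#' base is allowed, so an altered position keeps its residue 25% of the
#' time and the expected identity to the base is `100 - 0.75 * percent`
#' percent.
#'
#' @param base Base (target-identical) sequence, single RNA string.
#' @param percent Percentage of positions to randomize, in `[0, 100]`.
#' @param seed Optional integer seed.
#' @param name Construct name (default `"<my>MY"` with `my = percent / 2`,
#'   the simulated million-years of divergence under the 2% rule).
#' @return List of class `clock_construct`: `name`, `percent_randomized`,
#'   `sequence`, `altered_positions` (1-based), `seed`.
#' @export
generate_clock_construct <- function(base, percent, seed = NULL,
                                     name = NULL) {
  if (percent < 0 || percent > 100) {
    stop("percent must lie in [0, 100]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  base <- normalize_rna(base)
  len <- nchar(base)
  n_alt <- round(percent * len / 100)
  pos <- sort(sample.int(len, n_alt))
  chars <- strsplit(base, "", fixed = TRUE)[[1]]
  chars[pos] <- sample(c("A", "C", "G", "U"), n_alt, replace = TRUE)
  structure(list(
    name = name %||% paste0(format(percent / 2, trim = TRUE), "MY"),
    percent_randomized = percent,
    sequence = paste(chars, collapse = ""),
    altered_positions = pos,
    seed = seed), class = "clock_construct")
}

#' Generate a window construct
#'
#' Replaces positions `[window_start, window_start + window_len - 1]` of a
#' randomized backbone with the same-coordinate fragment of the base
#' sequence, producing a trigger that matches the target only over that
#' block.
#'
#' @param base Target-identical sequence.
#' @param window_start 1-based window start.
#' @param window_len Window length (0 returns the backbone unchanged).
#' @param backbone Randomized sequence of the same length as `base`.
#' @return Single RNA string.
#' @export
generate_window_construct <- function(base, window_start, window_len,
                                      backbone) {
  base <- normalize_rna(base); backbone <- normalize_rna(backbone)
  if (nchar(base) != nchar(backbone)) {
    stop("base and backbone must have equal length", call. = FALSE)
  }
  if (window_len == 0L) return(backbone)
  we <- window_start + window_len - 1L
  if (window_start < 1L || we > nchar(base)) {
    stop("window outside sequence bounds", call. = FALSE)
  }
  paste0(substr(backbone, 1L, window_start - 1L),
         substr(base, window_start, we),
         substr(backbone, we + 1L, nchar(backbone)))
}

#' Ungapped percent identity of two equal-length sequences
#'
#' @param a,b Sequences of equal length.
#' @return `100 * matches / length`.
#' @export
percent_identity <- function(a, b) {
  a <- normalize_rna(a); b <- normalize_rna(b)
  if (nchar(a) != nchar(b)) {
    stop("sequences must have equal length", call. = FALSE)
  }
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  100 * mean(ca == cb)
}

#' Generate the molecular-clock construct series
#'
#' The standard series spans 0-50 simulated million years: 2% steps up to
#' 10% randomized, then 10% steps to 100%.
#'
#' @param base Target-identical sequence.
#' @param percents Percentages to generate.
#' @param seed Integer seed (per-construct seeds are derived from it).
#' @return Named list of `clock_construct`.
#' @export
clock_series <- function(base,
                         percents = c(0, 2, 4, 6, 8, 10, seq(20, 100, 10)),
                         seed = 1L) {
  out <- lapply(seq_along(percents), function(i) {
    generate_clock_construct(base, percents[i], seed = seed * 1000L + i)
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Generate the window construct series
#'
#' Nonoverlapping windows of `window_len` nt along the base, each embedded
#' in the given fully randomized backbone; named `"<start>-<end>W"`.
#'
#' @param base Target-identical sequence.
#' @param backbone Fully randomized sequence of equal length.
#' @param window_len Window length (default 100).
#' @return Named character vector of construct sequences.
#' @export
window_series <- function(base, backbone, window_len = 100L) {
  len <- nchar(base)
  starts <- seq(1L, len - window_len + 1L, by = window_len)
  out <- vapply(starts, function(s) {
    generate_window_construct(base, s, window_len, backbone)
  }, character(1))
  names(out) <- sprintf("%d-%dW", starts, starts + window_len - 1L)
  out
}

#' Write a construct series as FASTA plus a manifest
#'
#' @param constructs Named list of `clock_construct` and/or named character
#'   sequences.
#' @param base Base sequence the constructs derive from (for identity).
#' @param out_dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Paths of the FASTA and manifest files, invisibly.
#' @export
write_construct_series <- function(constructs, base, out_dir,
                                   prefix = "constructs") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- vapply(constructs, function(x) {
    if (inherits(x, "clock_construct")) x$sequence else x
  }, character(1))
  fa <- file.path(out_dir, paste0(prefix, ".fasta"))
  write_fasta(seqs, fa)
  manifest <- data.frame(
    name = names(seqs),
    percent_randomized = vapply(constructs, function(x) {
      if (inherits(x, "clock_construct")) x$percent_randomized else NA_real_
    }, numeric(1)),
    n_altered = vapply(constructs, function(x) {
      if (inherits(x, "clock_construct")) length(x$altered_positions)
      else NA_integer_
    }, integer(1)),
    percent_identity_to_base = vapply(
      seqs, function(s) round(percent_identity(s, base), 1), numeric(1)),
    stringsAsFactors = FALSE)
  tsv <- file.path(out_dir, paste0(prefix, "_manifest.tsv"))
  utils::write.table(manifest, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fa, manifest = tsv))
}
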