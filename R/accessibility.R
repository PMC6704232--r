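# Local accessibility of target sites: probability that a u-nt stretch of
# the transcript is unpaired, computed with a windowed partition function.

#' Accessibility parameters
#'
#' @param u Length of the unpaired stretch (nt, default 8).
#' @param span_l Maximum base-pair span (nt, default 40).
#' @param window_w Folding window length (nt, default 80).
#' @param threshold Local accessibility probability (LAP) cutoff in
#'   `[0, 1]` (default 0.1).
#' @return List of class `accessibility_params`.
#' @export
accessibility_params <- function(u = 8L, span_l = 40L, window_w = 80L,
                                 threshold = 0.1) {
  u <- as.integer(u); span_l <- as.integer(span_l)
  window_w <- as.integer(window_w)
  if (!(u >= 1L && u <= span_l && span_l <= window_w)) {
    stop("accessibility parameters must satisfy 1 <= u <= span_l <= window_w",
         call. = FALSE)
  }
  if (threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]", call. = FALSE)
  }
  structure(list(u = u, span_l = span_l, window_w = window_w,
                 threshold = threshold),
            class = "accessibility_params")
}

#' Reduced folding energy model
#'
#' Secondary-structure ensemble model used for accessibility: canonical
#' pairs (AU, UA, CG, GC) plus GU/UG wobbles, hairpins with at least three
#' unpaired nucleotides. A pair stacked directly on its inner neighbor
#' contributes the nearest-neighbor stacking free energy (from
#' [nn_model()]; a single representative constant for stacks involving a
#' wobble pair); a pair closing a loop contributes a constant penalty.
#'
#' @param model A [nn_model()] providing the Watson-Crick stacks and RT.
#' @param loop_penalty Loop-closure penalty in kcal/mol (default 4.5;
#'   chosen so that a 4-bp GC-stem hairpin is strongly favored over the
#'   open chain at 37 degrees C).
#' @param wobble_stack Stacking free energy (kcal/mol) for any stack
#'   involving a GU pair (default -1.3).
#' @return List of class `fold_energy_model`.
#' @export
fold_energy_model <- function(model = nn_model(), loop_penalty = 4.5,
                              wobble_stack = -1.3) {
  bases <- c("A", "C", "G", "U")
  wc <- matrix(NA_real_, 4, 4, dimnames = list(bases, bases))
  for (x in bases) for (y in bases) wc[x, y] <- model$stacks[paste0(x, y)]
  structure(list(wcstack = wc, wobble_stack = wobble_stack,
                 loop_penalty = loop_penalty, rt = model$rt,
                 hairpin_min_unpaired = 3L),
            class = "fold_energy_model")
}

encode_rna <- function(seq) {
  m <- match(strsplit(seq, "", fixed = TRUE)[[1]],
             c("A", "C", "G", "U"))
  m[is.na(m)] <- 5L # ambiguous: cannot pair
  m - 1L
}

#' Local accessibility profile of a transcript
#'
#' For every sliding folding window of length `min(window_w, len)` a
#' McCaskill-style partition function restricted to pairs of span at most
#' `span_l` is computed under the reduced [fold_energy_model()]; the
#' Boltzmann probability that each `u`-stretch is completely unpaired is
#' averaged over all windows containing the stretch and stored at the
#' stretch's 3'-most position (positions `< u` are undefined, `NA`).
#'
#' @param seq Transcript sequence (single string, RNA alphabet) or a
#'   single named element; non-ACGU symbols are treated as unpairable.
#' @param params An [accessibility_params()].
#' @param model A [fold_energy_model()].
#' @param transcript_id Identifier stored with the profile.
#' @return Object of class `accessibility_profile`: list with
#'   `transcript_id`, `lap` (numeric vector, one value per position, in
#'   `[0, 1]` or `NA`), and `params`.
#' @examples
#' p <- partition_unpaired(strrep("A", 30), accessibility_params(u = 4))
#' all(p$lap[4:30] == 1)  # no pairs possible: fully accessible
#' @export
partition_unpaired <- function(seq, params = accessibility_params(),
                               model = fold_energy_model(),
                               transcript_id = NULL) {
  id <- transcript_id %||% names(seq) %||% "seq"
  s <- normalize_rna(unname(seq[1]))
  if (nchar(s) < params$u) {
    stop("sequence shorter than the unpaired-stretch length u", call. = FALSE)
  }
  lap <- plfold_lap_cpp(encode_rna(s), params$u, params$span_l,
                        params$window_w, model$wcstack, model$wobble_stack,
                        model$loop_penalty, model$rt)
  structure(list(transcript_id = id, lap = lap, params = params),
            class = "accessibility_profile")
}

#' @export
print.accessibility_profile <- function(x, ...) {
  ok <- !is.na(x$lap)
  cat(sprintf(
    "accessibility_profile for '%s': %d positions (u = %d), LAP %.3f-%.3f\n",
    x$transcript_id, length(x$lap), x$params$u,
    min(x$lap[ok]), max(x$lap[ok])))
  invisible(x)
}

#' Accessibility of one target site
#'
#' Scalar accessibility of the site `[site_start, site_start + k - 1]`
#' (1-based): the maximum defined LAP value over the site. Callers compare
#' it with `params$threshold`.
#'
#' @param profile An [partition_unpaired()] profile.
#' @param site_start 1-based start of the site on the transcript.
#' @param k Site length (siRNA length).
#' @return Maximum LAP over the site; `NA` if no position in the site has a
#'   defined value (site entirely within the first `u - 1` positions).
#' @export
site_accessibility <- function(profile, site_start, k) {
  n <- length(profile$lap)
  if (site_start < 1L || site_start + k - 1L > n) {
    stop("site [", site_start, ", ", site_start + k - 1L,
         "] outside profile bounds [1, ", n, "]", call. = FALSE)
  }
  v <- profile$lap[site_start:(site_start + k - 1L)]
  if (all(is.na(v))) return(NA_real_)
  max(v, na.rm = TRUE)
}

#' Write an accessibility profile as TSV
#'
#' Columns: `transcript_id`, `position` (1-based), `lap`.
#'
#' @param profile An `accessibility_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- data.frame(transcript_id = profile$transcript_id,
                   position = seq_along(profile$lap),
                   lap = format_num(profile$lap))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# fixed-format numbers so outputs are byte-stable across platforms
format_num <- function(x, digits = 6L) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
}
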