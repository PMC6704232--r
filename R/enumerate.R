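#' Enumerate all candidate siRNA duplexes from a trigger
#'
#' Slides a window of length `k` over the trigger (sense polarity, i.e. the
#' strand with the same sequence as the target mRNA) and emits one duplex
#' per window: the sense k-mer plus its reverse complement (the candidate
#' guide strand). Windows containing a non-A/C/G/U symbol are skipped; the
#' number skipped is attached as attribute `n_skipped_ambiguous`.
#'
#' @param trigger Trigger sequence: a single named character string, or an
#'   unnamed string with `trigger_id` supplied.
#' @param k siRNA length in nucleotides (default 21; allowed 19-25, bounds
#'   configurable via `k_bounds`).
#' @param trigger_id Identifier used in reports when `trigger` is unnamed.
#' @param k_bounds Allowed range for `k`.
#' @return A `data.frame` with columns `trigger_id`, `start` (1-based),
#'   `sense`, `antisense`; one row per duplex, ordered by `start`.
#' @examples
#' d <- enumerate_sirnas(c(trig = "ACGUACGUACGUACGUACGUACG"), k = 21)
#' nrow(d)  # 3
#' @export
enumerate_sirnas <- function(trigger, k = 21L, trigger_id = NULL,
                             k_bounds = c(19L, 25L)) {
  if (k < k_bounds[1] || k > k_bounds[2]) {
    stop("siRNA length k = ", k, " outside allowed range [",
         k_bounds[1], ", ", k_bounds[2], "]", call. = FALSE)
  }
  id <- trigger_id %||% names(trigger) %||% "trigger"
  seq <- normalize_rna(unname(trigger[1]))
  n <- nchar(seq)
  empty <- data.frame(trigger_id = character(), start = integer(),
                      sense = character(), antisense = character(),
                      stringsAsFactors = FALSE)
  if (n < k) {
    attr(empty, "n_skipped_ambiguous") <- 0L
    return(empty)
  }
  starts <- seq_len(n - k + 1L)
  sense <- substring(seq, starts, starts + k - 1L)
  keep <- !grepl("[^ACGU]", sense)
  out <- data.frame(trigger_id = id, start = starts[keep],
                    sense = sense[keep],
                    antisense = reverse_complement(sense[keep]),
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped_ambiguous") <- sum(!keep)
  out
}

#' Find all placements of siRNAs on a transcript database
#'
#' Matches both strands of every duplex against every transcript:
#' `sense-match` placements are occurrences of the sense k-mer (the
#' antisense strand would act as guide on that transcript), and
#' `antisense-match` placements are occurrences of the antisense k-mer.
#' Perfect matches use a k-mer hash join; 1-2 mismatches use a pigeonhole
#' seed-and-verify search (split the k-mer into `m + 1` pieces, locate
#' exact piece occurrences, verify the full window by Hamming distance).
#' The result is complete and duplicate-free.
#'
#' @param duplexes Output of [enumerate_sirnas()].
#' @param db A `transcript_db`.
#' @param max_mismatches Maximum Hamming mismatches, 0 (default), 1 or 2.
#' @return A `data.frame` with columns `trigger_id`, `sirna_start`, `sense`,
#'   `transcript_id`, `position` (1-based start on the transcript),
#'   `orientation` (`"sense-match"` / `"antisense-match"`), `mismatches`.
#' @export
find_hits <- function(duplexes, db, max_mismatches = 0L) {
  stopifnot(inherits(db, "transcript_db"))
  if (nrow(db$entries) == 0L) stop("empty transcript database", call. = FALSE)
  if (!max_mismatches %in% 0:2) {
    stop("max_mismatches must be 0, 1 or 2", call. = FALSE)
  }
  empty <- data.frame(trigger_id = character(), sirna_start = integer(),
                      sense = character(), transcript_id = character(),
                      position = integer(), orientation = character(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  if (nrow(duplexes) == 0L) return(empty)
  k <- nchar(duplexes$sense[1])

  queries <- data.table::data.table(
    trigger_id = rep(duplexes$trigger_id, 2L),
    sirna_start = rep(duplexes$start, 2L),
    sense = rep(duplexes$sense, 2L),
    kmer = c(duplexes$sense, duplexes$antisense),
    orientation = rep(c("sense-match", "antisense-match"),
                      each = nrow(duplexes)))

  hits <- if (max_mismatches == 0L) {
    exact_hits(queries, db, k)
  } else {
    pigeonhole_hits(queries, db, k, max_mismatches)
  }
  if (nrow(hits) == 0L) return(empty)
  data.table::setorder(hits, trigger_id, sirna_start, transcript_id,
                       position, orientation)
  as.data.frame(hits[, list(trigger_id, sirna_start, sense, transcript_id,
                            position, orientation, mismatches)])
}

# all k-length windows of every transcript as a data.table
kmer_index <- function(db, k) {
  parts <- lapply(seq_len(nrow(db$entries)), function(i) {
    s <- db$entries$seq[i]
    n <- nchar(s)
    if (n < k) return(NULL)
    starts <- seq_len(n - k + 1L)
    data.table::data.table(kmer = substring(s, starts, starts + k - 1L),
                           transcript_id = db$entries$id[i],
                           position = starts)
  })
  data.table::rbindlist(parts)
}

exact_hits <- function(queries, db, k) {
  idx <- kmer_index(db, k)
  if (nrow(idx) == 0L) return(idx[0])
  m <- merge(queries, idx, by = "kmer", allow.cartesian = TRUE)
  if (nrow(m) == 0L) return(m)
  m[, mismatches := 0L]
  m[, kmer := NULL]
  m
}

pigeonhole_hits <- function(queries, db, k, max_mm) {
  np <- max_mm + 1L
  cuts <- round(seq(0L, k, length.out = np + 1L))
  piece_off <- cuts[-length(cuts)] + 1L        # 1-based piece starts
  piece_len <- diff(cuts)

  cand <- data.table::rbindlist(lapply(seq_len(np), function(j) {
    idx <- kmer_index(db, piece_len[j])
    pieces <- data.table::data.table(
      qid = seq_len(nrow(queries)),
      piece = substring(queries$kmer, piece_off[j],
                        piece_off[j] + piece_len[j] - 1L))
    m <- merge(pieces, idx, by.x = "piece", by.y = "kmer",
               allow.cartesian = TRUE)
    if (nrow(m) == 0L) return(NULL)
    m[, position := position - piece_off[j] + 1L]
    m[, list(qid, transcript_id, position)]
  }))
  if (is.null(cand) || nrow(cand) == 0L) {
    return(data.table::data.table(
      trigger_id = character(), sirna_start = integer(), sense = character(),
      transcript_id = character(), position = integer(),
      orientation = character(), mismatches = integer()))
  }
  cand <- unique(cand)
  tlen <- setNames(nchar(db$entries$seq), db$entries$id)
  cand <- cand[position >= 1L & position + k - 1L <= tlen[transcript_id]]
  # verify: Hamming distance between query k-mer and the candidate window
  tseq <- setNames(db$entries$seq, db$entries$id)
  win <- substring(tseq[cand$transcript_id], cand$position,
                   cand$position + k - 1L)
  q <- queries$kmer[cand$qid]
  mm <- integer(nrow(cand))
  for (i in seq_len(k)) {
    mm <- mm + (substr(q, i, i) != substr(win, i, i))
  }
  cand[, mismatches := mm]
  cand <- cand[mismatches <= max_mm]
  res <- cbind(queries[cand$qid,
                       list(trigger_id, sirna_start, sense, orientation)],
               cand[, list(transcript_id, position, mismatches)])
  res
}

#' Count hits per transcript
#'
#' @param hits Output of [find_hits()].
#' @return A `data.frame` with columns `transcript_id`, `n_hits`, ordered by
#'   count (descending) then identifier.
#' @export
hits_per_transcript <- function(hits) {
  if (nrow(hits) == 0L) {
    return(data.frame(transcript_id = character(), n_hits = integer(),
                      stringsAsFactors = FALSE))
  }
  dt <- data.table::as.data.table(hits)
  out <- dt[, list(n_hits = .N), by = transcript_id]
  data.table::setorder(out, -n_hits, transcript_id)
  as.data.frame(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
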