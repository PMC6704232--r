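#' Read a FASTA file into a transcript database
#'
#' Parses a (multi-record) FASTA file of DNA or RNA sequences and returns a
#' validated transcript database. Sequences are normalized to the RNA
#' alphabet: case is folded to upper and `T` is mapped to `U`. IUPAC
#' ambiguity codes (`N`, `R`, ...) are retained; downstream siRNA windows
#' containing them are skipped. The original alphabet (DNA if any `T` was
#' seen, RNA otherwise) is recorded per entry.
#'
#' @param path Path to a FASTA file.
#' @return An object of class `transcript_db`: a list with
#'   * `entries` — a `data.frame` with columns `id`, `description`,
#'     `seq` (normalized RNA residues), `alphabet` (`"DNA"` or `"RNA"`),
#'   * `source_path` — the input path.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">t1 demo", "ACGTACGT"), fa)
#' db <- read_fasta(fa)
#' db$entries$seq  # "ACGUACGU"
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("malformed FASTA in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(set) == 0L) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate sequence identifier(s) in '", path, "': ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  raw <- as.character(set)
  if (any(nchar(raw) == 0L)) {
    stop("zero-length sequence record(s) in '", path, "': ",
         paste(ids[nchar(raw) == 0L], collapse = ", "), call. = FALSE)
  }
  norm <- normalize_rna(raw)
  alphabet <- ifelse(grepl("[Tt]", raw), "DNA", "RNA")
  new_transcript_db(
    data.frame(id = ids, description = desc, seq = norm,
               alphabet = alphabet, stringsAsFactors = FALSE),
    source_path = path
  )
}

new_transcript_db <- function(entries, source_path = NA_character_) {
  stopifnot(is.data.frame(entries),
            all(c("id", "seq") %in% names(entries)))
  if (is.null(entries$description)) entries$description <- ""
  if (is.null(entries$alphabet)) entries$alphabet <- "RNA"
  structure(list(entries = entries, source_path = source_path),
            class = "transcript_db")
}

#' Build a transcript database from in-memory sequences
#'
#' @param seqs Named character vector of nucleotide sequences (DNA or RNA).
#' @return A `transcript_db` (see [read_fasta()]).
#' @export
transcript_db <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("sequences must be named", call. = FALSE)
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence identifier(s)", call. = FALSE)
  }
  if (any(nchar(seqs) == 0L)) stop("zero-length sequence", call. = FALSE)
  alphabet <- ifelse(grepl("[Tt]", seqs), "DNA", "RNA")
  new_transcript_db(data.frame(
    id = names(seqs), description = "",
    seq = normalize_rna(unname(seqs)), alphabet = alphabet,
    stringsAsFactors = FALSE))
}

#' @export
print.transcript_db <- function(x, ...) {
  cat("transcript_db with", nrow(x$entries), "entries\n")
  n <- min(6L, nrow(x$entries))
  for (i in seq_len(n)) {
    cat(sprintf("  %s (%d nt, %s)\n", x$entries$id[i],
                nchar(x$entries$seq[i]), x$entries$alphabet[i]))
  }
  if (nrow(x$entries) > n) cat("  ...\n")
  invisible(x)
}

#' @export
length.transcript_db <- function(x) nrow(x$entries)

#' Look up a database entry by identifier
#'
#' @param db A `transcript_db`.
#' @param id Sequence identifier.
#' @return The normalized RNA sequence (single string).
#' @export
db_sequence <- function(db, id) {
  stopifnot(inherits(db, "transcript_db"))
  i <- match(id, db$entries$id)
  if (is.na(i)) stop("unknown transcript identifier: ", id, call. = FALSE)
  db$entries$seq[i]
}

#' Normalize nucleotide strings to the RNA alphabet
#'
#' Uppercases and maps `T` to `U`. Characters outside `A/C/G/U` (IUPAC
#' ambiguity codes) are kept; anything not a letter is rejected.
#'
#' @param x Character vector of sequences.
#' @return Character vector over the RNA alphabet.
#' @export
normalize_rna <- function(x) {
  out <- chartr("t", "u", toupper(x))
  out <- chartr("T", "U", out)
  bad <- grepl("[^ABCDGHKMNRSUVWY]", out)
  if (any(bad)) {
    stop("invalid characters in sequence(s): ",
         paste(head(which(bad), 3L), collapse = ", "), call. = FALSE)
  }
  out
}

#' Reverse complement of RNA sequences
#'
#' A pairs U, C pairs G; ambiguity codes map to their IUPAC complements
#' (N stays N). Vectorized; an involution.
#'
#' @param x Character vector of RNA sequences (normalized; see
#'   [normalize_rna()]).
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("ACGU")  # "ACGU"
#' reverse_complement("AAAA")  # "UUUU"
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGUNRYSWKMBDHV", "UGCANYRSWMKVHDB", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Write a transcript database (or named sequences) as FASTA
#'
#' Lines are wrapped at 60 columns. Sequences are written in their
#' normalized (RNA) form.
#'
#' @param x A `transcript_db` or a named character vector.
#' @param path Output file path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (inherits(x, "transcript_db")) {
    ids <- x$entries$id
    desc <- x$entries$description
    seqs <- x$entries$seq
    hdr <- ifelse(nzchar(desc), paste(ids, desc), ids)
  } else {
    seqs <- unname(x)
    hdr <- names(x)
  }
  set <- Biostrings::BStringSet(seqs)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
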