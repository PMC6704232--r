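# Independent oracles used by the property tests. Deliberately naive and
# separate from the package's algorithmic paths: a sliding-window Hamming
# scan for the matcher, and exhaustive secondary-structure enumeration
# with direct Boltzmann summation for the accessibility partition
# function.

# --- brute-force matcher -------------------------------------------------

hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

oracle_find_hits <- function(duplexes, db, max_mm) {
  rows <- list()
  for (d in seq_len(nrow(duplexes))) {
    k <- nchar(duplexes$sense[d])
    for (orient in c("sense-match", "antisense-match")) {
      q <- if (orient == "sense-match") duplexes$sense[d]
           else duplexes$antisense[d]
      for (t in seq_len(nrow(db$entries))) {
        s <- db$entries$seq[t]
        n <- nchar(s)
        if (n < k) next
        for (pos in seq_len(n - k + 1L)) {
          mm <- hamming(q, substr(s, pos, pos + k - 1L))
          if (mm <= max_mm) {
            rows[[length(rows) + 1L]] <- data.frame(
              trigger_id = duplexes$trigger_id[d],
              sirna_start = duplexes$start[d],
              sense = duplexes$sense[d],
              transcript_id = db$entries$id[t],
              position = pos, orientation = orient, mismatches = mm,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(trigger_id = character(), sirna_start = integer(),
                      sense = character(), transcript_id = character(),
                      position = integer(), orientation = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$trigger_id, out$sirna_start, out$transcript_id,
            out$position, out$orientation), , drop = FALSE]
}

hit_key <- function(h) {
  paste(h$trigger_id, h$sirna_start, h$transcript_id, h$position,
        h$orientation, h$mismatches, sep = "|")
}

# --- exhaustive-structure accessibility oracle ---------------------------

oracle_can_pair <- function(x, y) {
  paste0(x, y) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
}

oracle_is_wc <- function(x, y) {
  paste0(x, y) %in% c("AU", "UA", "CG", "GC")
}

# all nested pair sets over chars[i..j] (>=3 unpaired in hairpins,
# pair span <= span_l); each structure is a 2-column matrix of pairs
oracle_structures <- function(chars, span_l) {
  n <- length(chars)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i >= j) return(list(matrix(integer(), ncol = 2)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- lapply(rec(i + 1L, j), identity) # i unpaired
    ks <- if (j >= i + 4L) (i + 4L):min(j, i + span_l) else integer()
    for (k in ks) {
      if (!oracle_can_pair(chars[i], chars[k])) next
      for (a in rec(i + 1L, k - 1L)) {
        for (b in rec(k + 1L, j)) {
          out[[length(out) + 1L]] <- rbind(a, b, c(i, k))
        }
      }
    }
    memo[[key]] <- out
    out
  }
  rec(1L, n)
}

oracle_energy <- function(chars, pairs, model) {
  if (nrow(pairs) == 0L) return(0)
  key <- paste(pairs[, 1], pairs[, 2])
  e <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    stacked <- paste(i + 1L, j - 1L) %in% key
    if (stacked) {
      if (oracle_is_wc(chars[i], chars[j]) &&
          oracle_is_wc(chars[i + 1L], chars[j - 1L])) {
        e <- e + model$wcstack[chars[i], chars[i + 1L]]
      } else {
        e <- e + model$wobble_stack
      }
    } else {
      e <- e + model$loop_penalty
    }
  }
  e
}

# single-window LAP profile by direct Boltzmann summation; valid for
# sequences no longer than the folding window
oracle_lap <- function(seq, u, span_l, model) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  structs <- oracle_structures(chars, span_l)
  w <- vapply(structs, function(p) {
    exp(-oracle_energy(chars, p, model) / model$rt)
  }, numeric(1))
  z <- sum(w)
  lap <- rep(NA_real_, n)
  for (a in seq_len(n - u + 1L)) {
    b <- a + u - 1L
    free <- vapply(structs, function(p) {
      nrow(p) == 0L || !any(p[, 1] %in% a:b | p[, 2] %in% a:b)
    }, logical(1))
    lap[b] <- sum(w[free]) / z
  }
  lap
}

# --- shared fixtures -----------------------------------------------------

# deterministic small database builder
make_db <- function(lens, seed) {
  set.seed(seed)
  seqs <- vapply(lens, function(l) {
    paste(sample(c("A", "C", "G", "U"), l, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- paste0("tx", seq_along(seqs))
  transcript_db(seqs)
}
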