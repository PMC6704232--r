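# Workflow orchestration: off-target prediction (HS mode) and RNAi
# construct design (HE mode) with region-level reports.

#' Resolved run configuration
#'
#' Collects every tunable of the pipeline with its default. Defaults
#' follow standard practice for plant RNAi design: 21-nt siRNAs, perfect
#' matching, accessibility parameters u = 8 / span 40 / window 80 with a
#' LAP threshold of 0.1, and a 1 kcal/mol end-asymmetry margin.
#'
#' @param k siRNA length (19-25, default 21).
#' @param max_mismatches Matching tolerance, 0-2 (default 0).
#' @param u,span_l,window_w,lap_threshold Accessibility parameters, see
#'   [accessibility_params()].
#' @param dmfe_threshold Strict end-asymmetry margin in kcal/mol.
#' @param n_terminal Duplex-end window for stability (default 3).
#' @param region_length Recommended-region length in nt (default 100).
#' @param seed Optional integer seed recorded with the run.
#' @return List of class `run_config`.
#' @export
run_config <- function(k = 21L, max_mismatches = 0L, u = 8L, span_l = 40L,
                       window_w = 80L, lap_threshold = 0.1,
                       dmfe_threshold = 1, n_terminal = 3L,
                       region_length = 100L, seed = NULL) {
  cfg <- list(k = as.integer(k), max_mismatches = as.integer(max_mismatches),
              u = as.integer(u), span_l = as.integer(span_l),
              window_w = as.integer(window_w),
              lap_threshold = lap_threshold,
              dmfe_threshold = dmfe_threshold,
              n_terminal = as.integer(n_terminal),
              region_length = as.integer(region_length), seed = seed)
  if (cfg$k < 19L || cfg$k > 25L) stop("k must be in [19, 25]", call. = FALSE)
  if (!cfg$max_mismatches %in% 0:2) {
    stop("max_mismatches must be 0, 1 or 2", call. = FALSE)
  }
  # validates u <= span_l <= window_w and the threshold range
  accessibility_params(cfg$u, cfg$span_l, cfg$window_w, cfg$lap_threshold)
  structure(cfg, class = "run_config")
}

#' Apply a flat key-value config file and overrides to the defaults
#'
#' @param file Optional YAML (flat key-value) config file.
#' @param overrides Named list of values taking precedence over the file.
#' @return A [run_config()].
#' @export
load_run_config <- function(file = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file,
                                 call. = FALSE)
    vals <- yaml::read_yaml(file)
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, vals)
}

trigger_seq <- function(trigger, trigger_id) {
  id <- trigger_id %||% names(trigger) %||% "trigger"
  list(id = id, seq = normalize_rna(unname(trigger[1])))
}

empty_report <- function(trigger_id, mode, cfg) {
  structure(list(
    trigger_id = trigger_id, mode = mode, k = cfg$k, config = unclass(cfg),
    hits = data.frame(), positions = data.frame(
      position = integer(), total_hits = integer(), hs_hits = integer(),
      he_hits = integer(), zone = character()),
    transcripts = data.frame(
      transcript_id = character(), total = integer(), hs = integer(),
      he = integer(), is_main_target = logical()),
    recommended_region = NULL,
    log = list(n_enumerated = 0L, n_skipped_ambiguous = 0L, n_hits = 0L,
               n_hs = 0L, n_he = 0L)), class = "design_report")
}

# per-position siRNA counts and zoning shared by both modes
position_table <- function(len, k, duplexes, counted, hs_dup, he_dup,
                           red_dup) {
  total <- integer(len); hs <- integer(len); he <- integer(len)
  red <- logical(len)
  for (i in seq_len(nrow(duplexes))) {
    s <- duplexes$start[i]
    span <- s:(s + k - 1L)
    if (counted[i]) {
      total[span] <- total[span] + 1L
      if (hs_dup[i]) hs[span] <- hs[span] + 1L
      if (he_dup[i]) he[span] <- he[span] + 1L
    }
    if (red_dup[i]) red[span] <- TRUE
  }
  data.frame(position = seq_len(len), total_hits = total, hs_hits = hs,
             he_hits = he, zone = ifelse(red, "red", "green"),
             stringsAsFactors = FALSE)
}

transcript_summary <- function(hits, db, main_ids, rank_by = "hs") {
  ids <- db$entries$id
  count_on <- function(flag) {
    vapply(ids, function(t) sum(hits$transcript_id == t & flag), integer(1))
  }
  n <- nrow(hits)
  tab <- data.frame(
    transcript_id = ids,
    total = count_on(rep(TRUE, n)),
    hs = count_on(if (n) hits$hs_pass else logical(0)),
    he = count_on(if (n && !is.null(hits$he_pass)) hits$he_pass
                  else rep(FALSE, n)),
    is_main_target = ids %in% main_ids,
    stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[tab$total > 0L, , drop = FALSE]
  ord <- order(-tab[[rank_by]], -tab$total, tab$transcript_id)
  tab <- tab[ord, , drop = FALSE]
  row.names(tab) <- NULL
  tab
}

#' Off-target prediction (high-sensitivity mode)
#'
#' Enumerates siRNAs from the trigger, matches them against every
#' transcript, classifies each duplex with the HS rules (strand selection
#' only — no accessibility computation) and ranks transcripts by HS hit
#' count to expose putative off-targets.
#'
#' @param trigger Trigger sequence (named string, or `trigger_id` given).
#' @param db A `transcript_db`.
#' @param config A [run_config()].
#' @param trigger_id Identifier override.
#' @param model A [nn_model()].
#' @return A `design_report` (see [run_design_mode()] for fields); in this
#'   mode `he_hits` is 0 everywhere and all zones are green.
#' @export
run_offtarget_mode <- function(trigger, db, config = run_config(),
                               trigger_id = NULL, model = nn_model()) {
  tr <- trigger_seq(trigger, trigger_id)
  k <- config$k
  if (nchar(tr$seq) < k) {
    warning("trigger shorter than siRNA length; empty report")
    return(empty_report(tr$id, "offtarget", config))
  }
  duplexes <- enumerate_sirnas(tr$seq, k, trigger_id = tr$id)
  verdicts <- strand_selection(duplexes, model, config$n_terminal,
                               config$dmfe_threshold)
  hits <- find_hits(duplexes, db, config$max_mismatches)
  vi <- match(hits$sirna_start, verdicts$start)
  hits$hs_pass <- classify_hs(verdicts)[vi]
  hits$he_pass <- FALSE
  hits$delta_mfe <- verdicts$delta_mfe[vi]
  hits$site_lap <- NA_real_
  hits$failed_rules <- ""

  has_hit <- duplexes$start %in% hits$sirna_start
  hs_dup <- classify_hs(verdicts)
  rep <- empty_report(tr$id, "offtarget", config)
  rep$hits <- hits
  rep$positions <- position_table(nchar(tr$seq), k, duplexes,
                                  counted = has_hit,
                                  hs_dup = hs_dup & has_hit,
                                  he_dup = rep(FALSE, nrow(duplexes)),
                                  red_dup = rep(FALSE, nrow(duplexes)))
  rep$transcripts <- transcript_summary(hits, db, character(0),
                                        rank_by = "hs")
  rep$log <- list(
    n_enumerated = nrow(duplexes),
    n_skipped_ambiguous = attr(duplexes, "n_skipped_ambiguous"),
    n_hits = nrow(hits), n_hs = sum(hits$hs_pass), n_he = 0L)
  rep
}

#' RNAi construct design (high-efficiency mode)
#'
#' Matches the trigger's siRNAs against the database, computes
#' accessibility profiles for the declared main targets, classifies every
#' (siRNA, main-target hit) pair with the HE rules, zones each trigger
#' position green/red (red = at least one covering siRNA has an HS-mode
#' hit on a transcript outside the main-target set) and recommends the
#' region of `region_length` nt maximizing the HE-siRNA count subject to
#' zero red positions (ties broken by the 5'-most start).
#'
#' @inheritParams run_offtarget_mode
#' @param main_target_ids Identifiers of the intended target transcripts
#'   (a gene family may list several).
#' @return A `design_report`: list with `trigger_id`, `mode`, `k`,
#'   `config`, `hits` (classified hit table), `positions` (per-position
#'   `total_hits`/`hs_hits`/`he_hits`/`zone`), `transcripts` (per-target
#'   summary), `recommended_region` (`start`, `end`, `he_count` or NULL)
#'   and `log` (stage counts).
#' @export
run_design_mode <- function(trigger, db, main_target_ids,
                            config = run_config(), trigger_id = NULL,
                            model = nn_model()) {
  stopifnot(inherits(db, "transcript_db"))
  unknown <- setdiff(main_target_ids, db$entries$id)
  if (length(unknown)) {
    stop("unknown main target id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  tr <- trigger_seq(trigger, trigger_id)
  k <- config$k
  if (nchar(tr$seq) < k) {
    warning("trigger shorter than siRNA length; empty report")
    return(empty_report(tr$id, "design", config))
  }
  aparams <- accessibility_params(config$u, config$span_l, config$window_w,
                                  config$lap_threshold)
  fmodel <- fold_energy_model(model)
  duplexes <- enumerate_sirnas(tr$seq, k, trigger_id = tr$id)
  verdicts <- strand_selection(duplexes, model, config$n_terminal,
                               config$dmfe_threshold)
  hits <- find_hits(duplexes, db, config$max_mismatches)
  profiles <- lapply(setNames(main_target_ids, main_target_ids),
                     function(id) {
                       partition_unpaired(db_sequence(db, id), aparams,
                                          fmodel, transcript_id = id)
                     })
  hits <- classify_he_table(hits, verdicts, profiles, aparams, k)

  on_main <- hits$transcript_id %in% main_target_ids &
    hits$orientation == "sense-match"
  main_dup <- duplexes$start %in% hits$sirna_start[on_main]
  hs_dup <- classify_hs(verdicts)
  he_dup <- duplexes$start %in% hits$sirna_start[hits$he_pass]
  off_hs <- hits$hs_pass & !hits$transcript_id %in% main_target_ids
  red_dup <- duplexes$start %in% hits$sirna_start[off_hs]

  rep <- empty_report(tr$id, "design", config)
  rep$hits <- hits
  rep$positions <- position_table(nchar(tr$seq), k, duplexes,
                                  counted = main_dup,
                                  hs_dup = hs_dup & main_dup,
                                  he_dup = he_dup, red_dup = red_dup)
  rep$transcripts <- transcript_summary(hits, db, main_target_ids,
                                        rank_by = "he")
  rep$recommended_region <- recommend_region(
    rep$positions, duplexes$start[he_dup], k, config$region_length)
  rep$log <- list(
    n_enumerated = nrow(duplexes),
    n_skipped_ambiguous = attr(duplexes, "n_skipped_ambiguous"),
    n_hits = nrow(hits), n_hs = sum(hits$hs_pass),
    n_he = sum(hits$he_pass))
  rep
}

# best region of length region_length: max count of HE duplexes fully
# inside, zero red positions; NULL when no red-free region holds an HE siRNA
recommend_region <- function(positions, he_starts, k, region_length) {
  len <- nrow(positions)
  rl <- min(region_length, len)
  if (rl < k) return(NULL)
  red <- positions$zone == "red"
  best <- NULL
  for (s in seq_len(len - rl + 1L)) {
    if (any(red[s:(s + rl - 1L)])) next
    cnt <- sum(he_starts >= s & he_starts + k - 1L <= s + rl - 1L)
    if (cnt >= 1L && (is.null(best) || cnt > best$he_count)) {
      best <- list(start = s, end = s + rl - 1L, he_count = cnt)
    }
  }
  best
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf("design_report ('%s' mode) for trigger '%s'\n",
              x$mode, x$trigger_id))
  cat(sprintf("  siRNAs enumerated: %d (skipped ambiguous: %d)\n",
              x$log$n_enumerated, x$log$n_skipped_ambiguous))
  cat(sprintf("  hits: %d total, %d HS, %d HE\n",
              x$log$n_hits, x$log$n_hs, x$log$n_he))
  if (nrow(x$transcripts)) {
    cat("  top transcripts:\n")
    print(head(x$transcripts, 5), row.names = FALSE)
  }
  if (!is.null(x$recommended_region)) {
    cat(sprintf("  recommended region: %d-%d (%d HE siRNAs)\n",
                x$recommended_region$start, x$recommended_region$end,
                x$recommended_region$he_count))
  }
  invisible(x)
}

#' Export a design report
#'
#' Writes, into `out_dir`: the classified hit table
#' (`<trigger>_hits.tsv`), the per-position profile
#' (`<trigger>_positions.tsv`), a JSON summary (`<trigger>_summary.json`),
#' the resolved configuration (`config.yaml`) and a plot of the
#' total/HS/HE curves with red-zone shading (`<trigger>_profile.png`).
#' Identical reports export byte-identical TSV/JSON.
#'
#' @param report A `design_report`.
#' @param out_dir Output directory (created if needed).
#' @param plot Write the PNG plot (default TRUE).
#' @return Named character vector of written paths, invisibly.
#' @export
export_report <- function(report, out_dir, plot = TRUE) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ",
                                 out_dir, call. = FALSE)
  stem <- file.path(out_dir, gsub("[^A-Za-z0-9._-]", "_",
                                  report$trigger_id))
  hits_path <- paste0(stem, "_hits.tsv")
  hits <- report$hits
  if (nrow(hits)) {
    hits$delta_mfe <- format_num(hits$delta_mfe, 2L)
    hits$site_lap <- format_num(hits$site_lap, 6L)
    names(hits)[names(hits) == "sense"] <- "sense_sequence"
  } else {
    hits <- data.frame(trigger_id = character(), sirna_start = integer(),
                       sense_sequence = character(),
                       transcript_id = character(), position = integer(),
                       orientation = character(), mismatches = integer(),
                       hs_pass = logical(), he_pass = logical(),
                       delta_mfe = character(), site_lap = character(),
                       failed_rules = character())
  }
  utils::write.table(hits, hits_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pos_path <- paste0(stem, "_positions.tsv")
  utils::write.table(report$positions, pos_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  json_path <- paste0(stem, "_summary.json")
  jsonlite::write_json(report_to_list(report), json_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(report$config, cfg_path)
  out <- c(hits = hits_path, positions = pos_path, summary = json_path,
           config = cfg_path)
  if (plot) {
    png_path <- paste0(stem, "_profile.png")
    p <- plot_report(report)
    ggplot2::ggsave(png_path, p, width = 8, height = 4, dpi = 120)
    out <- c(out, plot = png_path)
  }
  invisible(out)
}

report_to_list <- function(report) {
  list(trigger_id = report$trigger_id, mode = report$mode, k = report$k,
       config = report$config[!vapply(report$config, is.null, logical(1))],
       positions = report$positions, transcripts = report$transcripts,
       recommended_region = report$recommended_region, log = report$log)
}

#' Read back an exported JSON summary
#'
#' @param path Path to a `*_summary.json` written by [export_report()].
#' @return The summary as a list (positions and transcripts as data
#'   frames), equal to `report_to_list()` of the exported report.
#' @export
import_report_summary <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Plot the per-position siRNA profile of a report
#'
#' Total, HS and HE siRNA counts per trigger position, with red-zone
#' shading for regions whose siRNAs hit transcripts outside the
#' main-target set.
#'
#' @param report A `design_report`.
#' @return A ggplot object.
#' @export
plot_report <- function(report) {
  pos <- report$positions
  long <- data.frame(
    position = rep(pos$position, 3L),
    count = c(pos$total_hits, pos$hs_hits, pos$he_hits),
    series = rep(c("total", "HS", "HE"), each = nrow(pos)))
  long$series <- factor(long$series, levels = c("total", "HS", "HE"))
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = position, y = count,
                                    colour = series))
  red <- pos$position[pos$zone == "red"]
  if (length(red)) {
    runs <- split(red, cumsum(c(1L, diff(red) != 1L)))
    shade <- data.frame(
      xmin = vapply(runs, min, numeric(1)) - 0.5,
      xmax = vapply(runs, max, numeric(1)) + 0.5)
    p <- p + ggplot2::geom_rect(
      data = shade, inherit.aes = FALSE,
      ggplot2::aes(xmin = xmin, xmax = xmax, ymin = -Inf, ymax = Inf),
      fill = "red", alpha = 0.15)
  }
  p + ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(total = "steelblue", HS = "darkorange", HE = "red3")) +
    ggplot2::labs(x = "trigger position (nt)", y = "siRNA count",
                  colour = NULL,
                  title = sprintf("%s (%s mode)", report$trigger_id,
                                  report$mode)) +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("count", "series", "xmin", "xmax"))
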