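# Nearest-neighbor duplex-end thermodynamics and strand-selection rules.
#
# Guide-strand loading by ARGONAUTE favors the strand whose 5' end sits in
# the thermodynamically less stable end of the duplex; the end stability is
# scored as the sum of nearest-neighbor stacking free energies of the
# terminal base pairs.

#' Load the nearest-neighbor stacking model
#'
#' Reads the Watson-Crick RNA dinucleotide stacking free energies
#' (dG37, kcal/mol; Xia/Turner parameter set) shipped with the package, or
#' a user-supplied table in the same two-column `stack<TAB>dg37` format.
#'
#' @param path Optional path to an alternative parameter table.
#' @return A list of class `nn_model` with
#'   * `stacks` — named numeric vector, one value per ordered dinucleotide,
#'   * `rt` — thermal energy at 37 degrees C (kcal/mol),
#'   * `temperature` — 37.
#' @export
nn_model <- function(path = NULL) {
  path <- path %||% system.file("extdata", "rna_nn_stacks_dg37.tsv",
                                package = "rnaitrigger")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  stacks <- setNames(tab$dg37, tab$stack)
  need <- as.vector(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"),
                          paste0))
  missing <- setdiff(need, names(stacks))
  if (length(missing)) {
    stop("stack table incomplete; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(stacks = stacks,
                 rt = 0.0019872041 * 310.15,
                 temperature = 37),
            class = "nn_model")
}

#' Free energy of a duplex end
#'
#' Sum of the `n_terminal - 1` nearest-neighbor stacking free energies of
#' the terminal base pairs at one duplex end, reading into the duplex from
#' the named strand's 5' terminus. More negative = more stable; the guide
#' strand is expected at the *less* stable (higher-MFE) 5' end.
#'
#' @param duplex One row of [enumerate_sirnas()] output (or any list with
#'   `sense` and `antisense` strings, fully complementary).
#' @param end `"antisense_5p"` or `"sense_5p"`.
#' @param n_terminal Number of terminal nucleotides (default 3, i.e. two
#'   stacks; allowed 2-5).
#' @param model A [nn_model()].
#' @return Free energy in kcal/mol.
#' @export
end_mfe <- function(duplex, end = c("antisense_5p", "sense_5p"),
                    n_terminal = 3L, model = nn_model()) {
  end <- match.arg(end)
  strand <- if (end == "antisense_5p") duplex$antisense else duplex$sense
  end_mfe_vec(strand, n_terminal, model)
}

# vectorized stack-sum over the first n_terminal nucleotides of each strand
end_mfe_vec <- function(strands, n_terminal, model) {
  if (n_terminal < 2L || n_terminal > 5L) {
    stop("n_terminal must be in [2, 5]", call. = FALSE)
  }
  total <- numeric(length(strands))
  for (i in seq_len(n_terminal - 1L)) {
    din <- substr(strands, i, i + 1L)
    e <- model$stacks[din]
    if (anyNA(e)) {
      stop("missing stack parameter for dinucleotide(s): ",
           paste(unique(din[is.na(e)]), collapse = ", "), call. = FALSE)
    }
    total <- total + unname(e)
  }
  total
}

#' Strand-selection verdicts for siRNA duplexes
#'
#' Applies the combined sequence- and thermodynamics-based guide-strand
#' selection rules to every duplex:
#' * sequence rule — U or A at the antisense (candidate guide) 5' terminus;
#' * opposite-end rule — G or C at the sense (passenger) 5' terminus
#'   (scored as a reinforcing flag, required by neither mode by default);
#' * thermodynamic rule — the guide 5' end is less stable than the
#'   passenger 5' end (`delta_mfe > 0`);
#' * strict thermodynamic rule — `delta_mfe` exceeds a margin
#'   (default 1 kcal/mol).
#'
#' `predicted_guide` is `"antisense"` if the sequence or the thermodynamic
#' rule favors the antisense strand, `"sense"` if only the mirror rules
#' favor the sense strand, `"undecided"` otherwise.
#'
#' @param duplexes Output of [enumerate_sirnas()].
#' @param model A [nn_model()].
#' @param n_terminal Terminal window size for end stability (default 3).
#' @param dmfe_threshold Margin (kcal/mol) for the strict rule (default 1).
#' @return `duplexes` with columns `guide_5p_mfe`, `passenger_5p_mfe`,
#'   `delta_mfe`, `sequence_rule_pass`, `opposite_end_rule_pass`,
#'   `thermo_rule_pass`, `strict_thermo_pass`, `predicted_guide` appended.
#' @export
strand_selection <- function(duplexes, model = nn_model(), n_terminal = 3L,
                             dmfe_threshold = 1) {
  if (nrow(duplexes) == 0L) {
    duplexes$guide_5p_mfe <- numeric()
    duplexes$passenger_5p_mfe <- numeric()
    duplexes$delta_mfe <- numeric()
    duplexes$sequence_rule_pass <- logical()
    duplexes$opposite_end_rule_pass <- logical()
    duplexes$thermo_rule_pass <- logical()
    duplexes$strict_thermo_pass <- logical()
    duplexes$predicted_guide <- character()
    return(duplexes)
  }
  g <- end_mfe_vec(duplexes$antisense, n_terminal, model)
  p <- end_mfe_vec(duplexes$sense, n_terminal, model)
  ant5 <- substr(duplexes$antisense, 1L, 1L)
  sen5 <- substr(duplexes$sense, 1L, 1L)
  delta <- g - p
  seq_rule <- ant5 %in% c("U", "A")
  opp_rule <- sen5 %in% c("G", "C")
  thermo <- delta > 0
  strict <- delta > dmfe_threshold
  ant_favored <- seq_rule | thermo
  sen_favored <- sen5 %in% c("U", "A") | delta < 0
  duplexes$guide_5p_mfe <- g
  duplexes$passenger_5p_mfe <- p
  duplexes$delta_mfe <- delta
  duplexes$sequence_rule_pass <- seq_rule
  duplexes$opposite_end_rule_pass <- opp_rule
  duplexes$thermo_rule_pass <- thermo
  duplexes$strict_thermo_pass <- strict
  duplexes$predicted_guide <- ifelse(ant_favored, "antisense",
                                     ifelse(sen_favored, "sense",
                                            "undecided"))
  duplexes
}
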