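# Candidate-peptide bookkeeping and screening analytics: the published
# candidate table for the CTLA4 cyclic-peptide design campaign, the
# bound-time vs MM-GBSA correlation, shortlisting rules and
# per-position amino-acid (sequence-logo) frequencies.

#' Candidate peptide table from the CTLA4 design campaign
#'
#' The 20 head-to-tail cyclic 17-mers evaluated against CTLA4: three
#' template entries (T0 with the original crystallographic coordinates
#' of the B7-2 fragment, T1/T2 redocked poses of the same sequence) and
#' 17 designed sequences. Columns: design score (opaque external
#' input), time bound in an unbiased screening simulation (ns; peptide
#' 16 remained bound for the full 2000 ns, flagged `censored`), the
#' MM-GBSA binding free energy with its SEM, and, for the two
#' shortlisted peptides, the rigorous standard binding free energy with
#' its half-split uncertainty.
#'
#' @return Data frame with columns `id`, `sequence`, `design_cycles`,
#'   `rosetta_score`, `time_bound`, `censored`, `dG_mmgbsa`,
#'   `dG_mmgbsa_sem`, `dG_rigorous`, `dG_rigorous_unc` and `designed`
#'   (FALSE for the template entries).
#' @export
ctla4_candidates <- function() {
  df <- data.frame(
    id = c("T0", "T1", "T2", as.character(1:17)),
    sequence = c(rep("CIIHHKKPTGMIRIHQM", 3),
                 "ECRYEPRPEGNILVSYS", "SIVTKLTPTGWVAASYS",
                 "KVEFKRTPSGTITVSME", "KVVYEPKPEGNIVVEYE",
                 "SAKFEPRPEGNIVVSYG", "EARYQPRPDGNVLVSYG",
                 "SAKWNPKPEGAELIEEG", "SAEFIPTPDGNLLKSSG",
                 "SIVVVLTPTGWVAASYS", "EIITKLTPTGWVAASYS",
                 "SIEMELTPTGWVNKSSS", "SIITVLTPTGWVAAEFS",
                 "DIITILTPTGYVAAAYS", "SIITVLTPTGWVAAYYS",
                 "SIQCVLTPTGWVAARYS", "EIDTVLTPTGWVAKRYS",
                 "SIRMELTPTGWVAAEYE"),
    design_cycles = c(0L, 0L, 0L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 2L,
                      2L, 2L, 3L, 3L, 3L, 3L, 3L),
    rosetta_score = c(172.4, 173.6, 170.8, 170.6, 175.1, 165.8, 194.3,
                      200.6, 206.0, 222.8, 214.0, 157.6, 157.6, 157.9,
                      155.7, 154.0, 155.3, 155.1, 153.8, 165.2),
    time_bound = c(61.3, 58.3, 90.8, 660.2, 899.4, 12.8, 48.4, 134.0,
                   245.0, 16.0, 13.8, 278.0, 86.2, 44.2, 1110.6, 395.6,
                   1463.2, 42.4, 2000.0, 119.4),
    censored = c(rep(FALSE, 18), TRUE, FALSE),
    dG_mmgbsa = c(-12.6, -16.4, -12.2, -22.7, -26.4, -10.4, -12.4, -22.7,
                  -14.2, -7.7, -8.8, -26.9, -19.3, -11.3, -32.8, -19.0,
                  -23.3, -20.3, -22.3, -18.5),
    dG_mmgbsa_sem = c(0.3, 0.5, 0.2, 0.2, 0.1, 0.6, 0.3, 0.2, 0.2, 0.7,
                      0.7, 0.3, 0.4, 0.3, 0.1, 0.2, 0.1, 0.7, 0.1, 0.4),
    dG_rigorous = c(rep(NA_real_, 14), -10.2, rep(NA_real_, 3), -6.6,
                    NA_real_),
    dG_rigorous_unc = c(rep(NA_real_, 14), 2.4, rep(NA_real_, 3), 3.5,
                        NA_real_),
    stringsAsFactors = FALSE
  )
  df$designed <- df$design_cycles > 0L
  df
}

#' Nine-stage free-energy table for the lead peptide
#'
#' The staged geometric-route results for binding of the lead designed
#' peptide to CTLA4: conformational and orientational restraints
#' applied to the free ligand (stages 1-2), the separation term for the
#' restrained complex (stage 3), and release of the directional,
#' orientational and conformational restraints on the bound ligand
#' (stages 4-9). Stage 2 is analytic (zero uncertainty).
#'
#' @return Data frame with columns `stage_id`, `system`, `action`,
#'   `term`, `free_energy`, `uncertainty`, `method`, `time_ns` (the
#'   simulation time behind each stage; metadata only).
#' @export
ctla4_stage_table <- function() {
  data.frame(
    stage_id = 1:9,
    system = c("ligand", "ligand", rep("complex", 7)),
    action = c("apply", "apply", "separation", rep("release", 6)),
    term = c("dG_apply_RMSD", "dG_apply_ThetaPhiPsi", "-kT ln(S* I C0)",
             "dG_release_phi", "dG_release_theta", "dG_release_Psi",
             "dG_release_Phi", "dG_release_Theta", "dG_release_RMSD"),
    free_energy = c(11.97, 6.61, -12.92, -0.49, -0.05, -0.20, -0.29,
                    -0.23, -11.03),
    uncertainty = c(2.96, 0.00, 0.79, 0.11, 0.01, 0.02, 0.17, 0.02, 1.59),
    method = c("eABF", "analytic", "REUS/WHAM", rep("eABF", 6)),
    time_ns = c(389, 0, 6956, 17, 20, 19, 17, 19, 91),
    stringsAsFactors = FALSE
  )
}

#' Correlation between bound time and MM-GBSA free energy
#'
#' Sample Pearson correlation between `time_bound` and the central
#' `dG_mmgbsa` values. Longer-bound peptides have more negative MM-GBSA
#' energies, so the signed correlation is negative; both the signed
#' value and its magnitude are returned.
#'
#' @param records Candidate data frame (see [ctla4_candidates()]).
#' @param subset "designed" (default; excludes the template entries),
#'   "all", or a logical/integer selector.
#' @return List with `r` (signed), `magnitude` and `n`.
#' @export
correlation_time_vs_energy <- function(records, subset = "designed") {
  sel <- if (identical(subset, "designed")) {
    if (is.null(records$designed)) rep(TRUE, nrow(records)) else
      records$designed
  } else if (identical(subset, "all")) rep(TRUE, nrow(records)) else subset
  df <- records[sel, , drop = FALSE]
  df <- df[is.finite(df$time_bound) & is.finite(df$dG_mmgbsa), ,
           drop = FALSE]
  if (nrow(df) < 3L) stop("need >= 3 records with both fields")
  if (stats::sd(df$time_bound) == 0 || stats::sd(df$dG_mmgbsa) == 0)
    stop("zero variance in a column; correlation undefined")
  r <- stats::cor(df$time_bound, df$dG_mmgbsa)
  list(r = r, magnitude = abs(r), n = nrow(df))
}

#' Shortlist candidates for rigorous free-energy calculation
#'
#' Returns the candidate(s) with the lowest MM-GBSA free energy and the
#' candidate(s) with the longest bound time. A censored record (still
#' bound when the simulation ended) outranks any uncensored record with
#' an equal or lower recorded time. Ties return all tied ids, ordered
#' by id.
#'
#' @param records Candidate data frame.
#' @return List with `lowest_mmgbsa` and `longest_bound` id vectors.
#' @export
shortlist <- function(records) {
  if (!nrow(records)) stop("no candidate records")
  lo <- records$id[records$dG_mmgbsa == min(records$dG_mmgbsa)]
  cens <- if (is.null(records$censored)) rep(FALSE, nrow(records)) else
    records$censored
  # censored times outrank equal (or smaller) uncensored times
  eff <- records$time_bound + ifelse(cens, 1e-9, 0)
  hi <- records$id[eff == max(eff)]
  list(lowest_mmgbsa = sort(lo), longest_bound = sort(hi))
}

#' Per-position amino-acid frequency matrix
#'
#' The matrix behind a sequence logo: for each position of an aligned,
#' equal-length set of sequences, the relative frequency of each of the
#' 20 canonical amino acids.
#'
#' @param sequences Character vector of equal-length sequences using
#'   the 20 canonical one-letter codes.
#' @return A `logo_matrix`: positions x 20 matrix (rows sum to 1) with
#'   attribute `n_sequences`.
#' @export
logo_frequencies <- function(sequences) {
  if (!length(sequences)) stop("no sequences")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop("sequences differ in length: ",
         paste(which(lens != lens[1]), collapse = ", "))
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  chars <- do.call(rbind, strsplit(sequences, ""))
  if (!all(chars %in% alphabet))
    stop("non-canonical letters: ",
         paste(unique(chars[!chars %in% alphabet]), collapse = ", "))
  m <- t(apply(chars, 2L, function(col)
    table(factor(col, levels = alphabet)) / length(col)))
  dimnames(m) <- list(position = seq_len(ncol(chars)), aa = alphabet)
  attr(m, "n_sequences") <- length(sequences)
  class(m) <- c("logo_matrix", class(m))
  m
}

#' Write / read a candidate table as TSV
#'
#' Lossless round-trip of the candidate bookkeeping, with censored
#' bound times marked by a trailing `*` on the `time_bound` field (the
#' footnote convention for "still bound at simulation end").
#'
#' @param records Candidate data frame.
#' @param path File path.
#' @return `path` invisibly (writer); the candidate data frame
#'   (reader).
#' @export
write_candidate_table <- function(records, path) {
  out <- records
  out$time_bound <- ifelse(!is.null(out$censored) & out$censored,
                           paste0(out$time_bound, "*"), out$time_bound)
  out$censored <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_candidate_table
#' @export
read_candidate_table <- function(path) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = "")
  tb$censored <- grepl("\\*$", tb$time_bound)
  tb$time_bound <- as.numeric(sub("\\*$", "", tb$time_bound))
  for (cl in c("design_cycles", "rosetta_score", "dG_mmgbsa",
               "dG_mmgbsa_sem", "dG_rigorous", "dG_rigorous_unc")) {
    if (!is.null(tb[[cl]])) tb[[cl]] <- as.numeric(tb[[cl]])
  }
  if (!is.null(tb$designed)) tb$designed <- as.logical(tb$designed)
  tb[, union(intersect(names(ctla4_candidates()), names(tb)),
             names(tb))]
}
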