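# Sequence-level physicochemical descriptors. All of gravy(), aromaticity(),
# net_charge() and nitrogen_count() are composition-based and therefore
# invariant under residue permutation.

.as_pepseq <- function(seq) {
  if (inherits(seq, "peptide_sequence")) return(seq)
  peptide_sequence(seq)
}

#' Grand average of hydropathy (GRAVY)
#'
#' Arithmetic mean of the Kyte-Doolittle residue hydropathies over the sequence.
#'
#' @param seq a [peptide_sequence] or a plain sequence string.
#' @return dimensionless mean hydropathy.
#' @export
gravy <- function(seq) {
  seq <- .as_pepseq(seq)
  mean(.KD_SCALE[seq$residues])
}

#' Aromatic residue content (AROM)
#'
#' Fraction of Phe, Trp and Tyr residues (His excluded, matching the ProtParam
#' convention).
#'
#' @inheritParams gravy
#' @return fraction in \[0, 1\].
#' @export
aromaticity <- function(seq) {
  seq <- .as_pepseq(seq)
  mean(seq$residues %in% .AROMATIC)
}

#' Net formal charge at neutral pH
#'
#' Integer formal charge: +1 per Arg/Lys, -1 per Asp/Glu, His neutral, +1 for a
#' free N-terminal amine and -1 for a free (non-amidated) C-terminal carboxyl.
#'
#' @inheritParams gravy
#' @return integer charge in elementary units.
#' @export
net_charge <- function(seq) {
  seq <- .as_pepseq(seq)
  side <- .SIDECHAIN_CHARGE[seq$residues]
  q <- sum(side, na.rm = TRUE)
  if (seq$n_terminal_free_amine) q <- q + 1L
  if (!seq$c_terminal_amide) q <- q - 1L
  as.integer(q)
}

#' Nitrogen atom count
#'
#' One backbone nitrogen per residue plus side-chain nitrogens (Arg 3, Lys 1,
#' His 2, Asn 1, Gln 1, Trp 1) plus one for a C-terminal amide. Used e.g. to
#' predict the mass shift of a uniformly 15N-labelled peptide.
#'
#' @inheritParams gravy
#' @return integer atom count.
#' @export
nitrogen_count <- function(seq) {
  seq <- .as_pepseq(seq)
  n <- length(seq$residues) + sum(.SIDECHAIN_N[seq$residues], na.rm = TRUE)
  if (seq$c_terminal_amide) n <- n + 1L
  as.integer(n)
}

#' Peptide molecular mass
#'
#' Sum of residue masses plus water, minus two hydrogen atoms per disulfide
#' bond. For a uniformly 15N-labelled peptide the 14N/15N mass difference is
#' added once per nitrogen atom. A C-terminal amide replaces -OH by -NH2
#' (net \eqn{-0.98402} Da monoisotopic).
#'
#' Note that theoretical masses quoted in the literature often do not state
#' whether they are monoisotopic or average; this function computes either and
#' callers should compare with an appropriate tolerance.
#'
#' @inheritParams gravy
#' @param mode `"mono"` (monoisotopic) or `"average"`.
#' @param mh_plus if `TRUE`, return the \[M+H\]+ ion mass (adds one proton).
#' @return mass in Da.
#' @export
molecular_mass <- function(seq, mode = c("mono", "average"), mh_plus = FALSE) {
  seq <- .as_pepseq(seq)
  mode <- match.arg(mode)
  tab <- if (mode == "mono") .MASS_MONO else .MASS_AVG
  water <- if (mode == "mono") .MASS_H2O_MONO else .MASS_H2O_AVG
  m <- sum(tab[seq$residues]) + water
  m <- m - 2 * .MASS_H_ATOM * length(seq$disulfide_pairs)
  if (seq$c_terminal_amide) {
    # -OH -> -NH2: -O -H +N +2H = +N +H -O
    m <- m + (14.0030740 + .MASS_H_ATOM - 15.9949146)
  }
  if (seq$label_n15) m <- m + .MASS_D15N * nitrogen_count(seq)
  if (mh_plus) m <- m + .MASS_PROTON
  m
}

#' Descriptor table for a set of peptides
#'
#' @param seqs a list of [peptide_sequence] objects (e.g. from [read_fasta()]).
#' @return a data frame with one row per peptide: `peptide_id`, `length`,
#'   `gravy`, `arom`, `charge`, `n_nitrogen`, `mass_mono`, `mass_avg`.
#' @export
peptide_descriptors <- function(seqs) {
  if (inherits(seqs, "peptide_sequence")) seqs <- list(seqs)
  data.frame(
    peptide_id = vapply(seqs, function(s) s$id, character(1)),
    length = vapply(seqs, function(s) length(s$residues), integer(1)),
    gravy = vapply(seqs, gravy, numeric(1)),
    arom = vapply(seqs, aromaticity, numeric(1)),
    charge = vapply(seqs, net_charge, integer(1)),
    n_nitrogen = vapply(seqs, nitrogen_count, integer(1)),
    mass_mono = vapply(seqs, molecular_mass, numeric(1), mode = "mono"),
    mass_avg = vapply(seqs, molecular_mass, numeric(1), mode = "average"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Censor out-of-range minimal hemolytic concentrations
#'
#' Activity values reported only as a lower bound (e.g. ">128 uM") are replaced
#' by a fixed surrogate so that they can participate in log-scale correlations.
#' Values reported as plain numbers pass through unchanged regardless of
#' magnitude.
#'
#' @param records a data frame with columns `mhc` (numeric or character; strings
#'   like `">128"` are recognised as censored bounds) and optionally `censored`
#'   (logical).
#' @param threshold the censoring threshold in uM (recorded in the output
#'   attributes; bounds in the data drive the censoring, not this value).
#' @param replacement surrogate concentration in uM assigned to censored
#'   records.
#' @return the data frame with numeric `mhc`, logical `censored`, and a
#'   `log_mhc` (log10) column.
#' @export
censor_mhc <- function(records, threshold = 128, replacement = 150) {
  if (!is.data.frame(records) || !("mhc" %in% names(records)))
    stop("records must be a data frame with an 'mhc' column", call. = FALSE)
  mhc_raw <- records$mhc
  censored <- if ("censored" %in% names(records)) isTRUE_vec(records$censored)
              else rep(FALSE, nrow(records))
  if (is.character(mhc_raw) || is.factor(mhc_raw)) {
    mhc_raw <- as.character(mhc_raw)
    is_bound <- grepl("^\\s*>", mhc_raw)
    censored <- censored | is_bound
    mhc_num <- suppressWarnings(as.numeric(sub("^\\s*>", "", mhc_raw)))
  } else {
    mhc_num <- as.numeric(mhc_raw)
  }
  if (anyNA(mhc_num) || any(mhc_num <= 0))
    stop("all MHC values must be positive concentrations", call. = FALSE)
  mhc_num[censored] <- replacement
  records$mhc <- mhc_num
  records$censored <- censored
  records$log_mhc <- log10(mhc_num)
  attr(records, "mhc_threshold") <- threshold
  attr(records, "mhc_replacement") <- replacement
  records
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  x %in% c("1", "TRUE", "true", "yes", 1)
}
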