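# Sequence-based peptide physicochemical properties and the staged
# virtual-screening funnel.

# average and monoisotopic residue masses (Da) for the 20 standard residues
.residue_mass <- list(
  average = c(G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167,
              V = 99.1326, T = 101.1051, C = 103.1388, L = 113.1594,
              I = 113.1594, N = 114.1038, D = 115.0886, Q = 128.1307,
              K = 128.1741, E = 129.1155, M = 131.1926, H = 137.1411,
              F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132),
  monoisotopic = c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
                   V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
                   I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
                   K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
                   F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
)
.water_mass <- c(average = 18.0153, monoisotopic = 18.010565)

#' Default pKa table for peptide charge calculations
#'
#' Side-chain pKa values (Lehninger-style) for the ionizable residues plus
#' the free alpha-amino and alpha-carboxyl terminal pKas used by
#' [net_charge()] and [isoelectric_point()]. Any entry can be overridden:
#' pI values from different published pKa sets typically differ by a few
#' tenths of a pH unit, so comparisons with external calculators should be
#' tolerance-based.
#'
#' @param ... Named overrides, e.g. `Y = 10.46` or `n_term = 8.6`. Valid
#'   names: `D, E, C, Y, H, K, R, n_term, c_term`.
#' @return Named numeric vector of pKa values.
#' @export
default_pka_table <- function(...) {
  pka <- c(D = 3.65, E = 4.25, C = 8.18, Y = 10.07, H = 6.00,
           K = 10.53, R = 12.48, n_term = 9.00, c_term = 3.55)
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(pka))
    if (length(bad)) stop("unknown pKa entries: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    if (any(ov <= 0 | ov >= 14)) stop("pKa values must lie in (0, 14)", call. = FALSE)
    pka[names(ov)] <- ov
  }
  pka
}

# validate and split a one-letter sequence; errors name the bad character
split_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence)) {
    stop("'sequence' must be a single non-empty string", call. = FALSE)
  }
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!aa %in% names(.residue_mass$average))
  if (length(bad)) {
    stop(sprintf("invalid residue letter '%s' at position %d in sequence '%s'",
                 aa[bad[1]], bad[1], sequence), call. = FALSE)
  }
  aa
}

#' Peptide mass from sequence
#'
#' Sum of residue masses plus one water. Additive over concatenation:
#' mass(s1 s2) = mass(s1) + mass(s2) - water.
#'
#' @param sequence One-letter amino-acid string (case-insensitive).
#' @param type `"average"` (default) or `"monoisotopic"`.
#' @return Mass in Da.
#' @examples
#' peptide_mass("FEGLFR")  # about 767.88 Da
#' @export
peptide_mass <- function(sequence, type = c("average", "monoisotopic")) {
  type <- match.arg(type)
  aa <- split_sequence(sequence)
  sum(.residue_mass[[type]][aa]) + .water_mass[[type]]
}

#' Henderson-Hasselbalch net charge of a peptide
#'
#' Fractional net charge at a given pH, summing the protonated fraction of
#' the positive groups (N-terminus, K, R, H side chains) minus the
#' deprotonated fraction of the negative groups (C-terminus, D, E, C, Y
#' side chains):
#' \deqn{z(pH) = \sum_{+} \frac{10^{pK_a}}{10^{pK_a} + 10^{pH}}
#'             - \sum_{-} \frac{10^{pH}}{10^{pK_a} + 10^{pH}}.}
#' Strictly decreasing in pH for every sequence.
#'
#' @param sequence One-letter amino-acid string.
#' @param ph pH in [0, 14].
#' @param pka pKa table, see [default_pka_table()].
#' @return Signed fractional charge.
#' @examples
#' round(net_charge("QLPSYR", 7))  # +1
#' @export
net_charge <- function(sequence, ph, pka = default_pka_table()) {
  if (any(ph < 0 | ph > 14)) stop("'ph' must lie in [0, 14]", call. = FALSE)
  aa <- split_sequence(sequence)
  pos <- c(pka[["n_term"]], pka[match(aa[aa %in% c("K", "R", "H")], names(pka))])
  neg <- c(pka[["c_term"]], pka[match(aa[aa %in% c("D", "E", "C", "Y")], names(pka))])
  vapply(ph, function(p) {
    sum(10^pos / (10^pos + 10^p)) - sum(10^p / (10^neg + 10^p))
  }, numeric(1))
}

#' Isoelectric point by bisection
#'
#' Solves `net_charge(sequence, pH) == 0` by bisection on [0, 14]. The
#' charge function is continuous and strictly decreasing, positive at pH 0
#' (all groups protonated) and negative at pH 14, so a unique root exists
#' for every valid sequence.
#'
#' @param sequence One-letter amino-acid string.
#' @param pka pKa table, see [default_pka_table()].
#' @param tol Bisection tolerance on pH (default 1e-4).
#' @return The pI in pH units; the returned value satisfies
#'   `abs(net_charge(sequence, pI)) < 1e-3`.
#' @examples
#' isoelectric_point("QLPSYR")  # about 9.5
#' @export
isoelectric_point <- function(sequence, pka = default_pka_table(), tol = 1e-4) {
  lo <- 0; hi <- 14
  f_lo <- net_charge(sequence, lo, pka)
  f_hi <- net_charge(sequence, hi, pka)
  if (f_lo <= 0 || f_hi >= 0) {
    stop("net charge does not change sign on [0, 14]", call. = FALSE)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(sequence, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Screening-funnel configuration
#'
#' Thresholds of the staged virtual-screening funnel applied to de-novo
#' peptide identification tables. All comparisons are strict inequalities.
#' Defaults: mass < 1000 Da, ALC > 80 %, relative peak area > 1e5,
#' predicted bioactivity score > 0.5, plus non-toxicity and good-solubility
#' requirements.
#'
#' @param max_mass Mass cut-off (Da), strict `<`.
#' @param min_alc Average Local Confidence cut-off (percent), strict `>`.
#' @param min_area Relative peak-area cut-off, strict `>`.
#' @param min_bioactivity Bioactivity-score cut-off (fraction), strict `>`.
#' @param require_nontoxic,require_soluble Logical stage switches.
#' @param mass_source `"observed"`: use the `mass` column when present and
#'   fall back to the computed average mass; `"computed"`: always compute
#'   from the sequence.
#' @param missing `"strict"`: a record lacking a field a stage needs is an
#'   error; `"lenient"`: the record passes that stage with a warning.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(max_mass = 1000, min_alc = 80, min_area = 1e5,
                          min_bioactivity = 0.5, require_nontoxic = TRUE,
                          require_soluble = TRUE,
                          mass_source = c("observed", "computed"),
                          missing = c("strict", "lenient")) {
  vals <- c(max_mass, min_alc, min_area, min_bioactivity)
  if (any(!is.finite(vals))) stop("thresholds must be finite", call. = FALSE)
  structure(list(max_mass = max_mass, min_alc = min_alc, min_area = min_area,
                 min_bioactivity = min_bioactivity,
                 require_nontoxic = isTRUE(require_nontoxic),
                 require_soluble = isTRUE(require_soluble),
                 mass_source = match.arg(mass_source),
                 missing = match.arg(missing)),
            class = "screen_config")
}

# one funnel stage: keep[i] from the per-record value and a predicate;
# NA handling per the missing-data policy
stage_keep <- function(values, pass, field, ids, policy) {
  miss <- is.na(values)
  keep <- !miss & pass(values)
  if (any(miss)) {
    if (policy == "strict") {
      stop(sprintf("record '%s' is missing required field '%s'",
                   ids[which(miss)[1]], field), call. = FALSE)
    }
    warning(sprintf("%d record(s) missing '%s'; passed through (lenient policy)",
                    sum(miss), field))
    keep[miss] <- TRUE
  }
  keep
}

#' Staged virtual screening of peptide records
#'
#' Applies the screening funnel to a peptide table: molecular mass, ALC,
#' relative peak area, predicted bioactivity score, toxicity and
#' solubility, in that order. Each stage removes the records failing its
#' strict threshold; the final survivor set is independent of both record
#' order and stage order (stages are independent filters).
#'
#' External predictors (bioactivity, toxicity, solubility) are not
#' re-implemented: by default their values are read from the `ranker`,
#' `toxin` and `solubility` columns, and a `score_provider` callable can
#' supply or override them.
#'
#' @param records Data.frame with column `sequence` and optional columns
#'   `mass` (Da), `alc` (percent), `area`, `ranker` (bioactivity score in
#'   [0, 1]), `toxin` (labels; `"Non-Toxin"` passes), `solubility`
#'   (`"good"` passes). Extra columns are ignored.
#' @param config A [screen_config()].
#' @param score_provider Optional `function(records)` returning a
#'   data.frame with any of `ranker`, `toxin`, `solubility` to override the
#'   input columns.
#' @return An object of class `funnel_report`: `stages` (data.frame with
#'   stage name, records entering and surviving), `survivors` (the
#'   surviving rows), and `surviving_ids` per stage.
#' @export
screen_peptides <- function(records, config = screen_config(),
                            score_provider = NULL) {
  stopifnot(inherits(config, "screen_config"))
  if (!is.data.frame(records) || !nrow(records)) {
    stop("'records' must be a non-empty data.frame", call. = FALSE)
  }
  if (!"sequence" %in% names(records)) {
    stop("'records' must have a 'sequence' column", call. = FALSE)
  }
  invisible(lapply(records$sequence, split_sequence))
  if (!is.null(score_provider)) {
    sc <- score_provider(records)
    for (col in intersect(c("ranker", "toxin", "solubility"), names(sc))) {
      records[[col]] <- sc[[col]]
    }
  }
  ids <- records$sequence
  col_or_na <- function(col) {
    if (col %in% names(records)) records[[col]] else rep(NA, nrow(records))
  }

  mass <- if (config$mass_source == "computed") {
    vapply(records$sequence, peptide_mass, numeric(1))
  } else {
    obs <- as.numeric(col_or_na("mass"))
    comp <- vapply(records$sequence, peptide_mass, numeric(1))
    ifelse(is.na(obs), comp, obs)
  }

  stages <- list(
    mass = function(k) stage_keep(mass[k], function(v) v < config$max_mass,
                                  "mass", ids[k], config$missing),
    alc = function(k) stage_keep(as.numeric(col_or_na("alc"))[k],
                                 function(v) v > config$min_alc,
                                 "alc", ids[k], config$missing),
    peak_area = function(k) stage_keep(as.numeric(col_or_na("area"))[k],
                                       function(v) v > config$min_area,
                                       "area", ids[k], config$missing),
    bioactivity = function(k) stage_keep(as.numeric(col_or_na("ranker"))[k],
                                         function(v) v > config$min_bioactivity,
                                         "ranker", ids[k], config$missing),
    toxicity = function(k) {
      v <- as.character(col_or_na("toxin"))[k]
      stage_keep(v, function(x) toupper(x) %in% c("NON-TOXIN", "NONTOXIN", "NON-TOXIC"),
                 "toxin", ids[k], config$missing)
    },
    solubility = function(k) {
      v <- as.character(col_or_na("solubility"))[k]
      stage_keep(v, function(x) tolower(x) == "good",
                 "solubility", ids[k], config$missing)
    }
  )
  if (!config$require_nontoxic) stages$toxicity <- NULL
  if (!config$require_soluble) stages$solubility <- NULL

  alive <- seq_len(nrow(records))
  tab <- data.frame(stage = character(), n_in = integer(), n_out = integer(),
                    stringsAsFactors = FALSE)
  surviving_ids <- list()
  for (nm in names(stages)) {
    n_in <- length(alive)
    keep <- stages[[nm]](alive)
    alive <- alive[keep]
    tab <- rbind(tab, data.frame(stage = nm, n_in = n_in, n_out = length(alive)))
    surviving_ids[[nm]] <- ids[alive]
  }
  structure(list(stages = tab,
                 survivors = records[alive, , drop = FALSE],
                 surviving_ids = surviving_ids),
            class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Screening funnel\n")
  print(x$stages, row.names = FALSE)
  cat("Final survivors:",
      if (nrow(x$survivors)) paste(x$survivors$sequence, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}
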