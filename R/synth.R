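# Seeded simulators with known ground truth for every input the pipeline
# consumes: kinetic traces, Box-Behnken response tables, peptide ID tables.
# Each generator is a pure function of its arguments and seed.

#' Simulate a kinetic absorbance trace with known initial rate
#'
#' Generates a progress curve from a declared family plus i.i.d. Gaussian
#' noise, at the usual plate-reader cadence (one reading every 10 s for
#' 10 min, 61 points). The generating initial rate is returned alongside
#' the trace so rate-recovery can be checked exactly.
#'
#' @param seed Integer RNG seed.
#' @param rate True initial rate, AU/min.
#' @param a0 Absorbance at t = 0 (AU).
#' @param curvature Quadratic coefficient (AU/min^2) for the quadratic
#'   family; ignored otherwise.
#' @param plateau Plateau absorbance for the exponential family.
#' @param duration Trace length in minutes.
#' @param interval Sampling interval in seconds.
#' @param sd Gaussian noise standard deviation (AU); 0 gives a noiseless
#'   trace.
#' @param family Generating curve family: `"quadratic"`, `"linear"` or
#'   `"exponential"`.
#' @return A list with `trace` (a [kinetic_trace()], times in seconds) and
#'   `true_rate` (AU/min).
#' @export
sim_kinetic_trace <- function(seed, rate = 0.02, a0 = 0.10,
                              curvature = -5e-4, plateau = 0.45,
                              duration = 10, interval = 10, sd = 0.002,
                              family = c("quadratic", "linear", "exponential")) {
  family <- match.arg(family)
  if (sd < 0) stop("'sd' must be >= 0", call. = FALSE)
  set.seed(seed)
  t_s <- seq(0, duration * 60, by = interval)
  t_min <- t_s / 60
  mu <- switch(family,
    quadratic = a0 + rate * t_min + curvature * t_min^2,
    linear = a0 + rate * t_min,
    exponential = {
      if (plateau <= a0) stop("'plateau' must exceed 'a0'", call. = FALSE)
      k <- rate / (plateau - a0)
      plateau - (plateau - a0) * exp(-k * t_min)
    })
  y <- mu + stats::rnorm(length(t_s), 0, sd)
  list(trace = kinetic_trace(t_s, y, time_unit = "s"), true_rate = rate)
}

#' Simulate Box-Behnken responses from a known quadratic surface
#'
#' Evaluates one or more known 10-coefficient second-order surfaces (coded
#' units, term order: intercept, 3 linear, AB, AC, BC, 3 quadratic) at the
#' runs of a 3-factor Box-Behnken design and adds Gaussian noise. With
#' `sd = 0`, [fit_quadratic()] recovers the generating coefficients to
#' numerical precision.
#'
#' @param factors A [bbd_factors()] specification.
#' @param coefficients Numeric vector of 10 true coefficients, or a named
#'   list of such vectors (one response column per element).
#' @param sd Noise standard deviation, recycled per response.
#' @param n_center Number of center replicates.
#' @param seed Integer RNG seed.
#' @return A `bbd_design` data.frame with one response column per surface;
#'   the generating coefficients are attached as attribute
#'   `"true_coefficients"`.
#' @export
sim_bbd_responses <- function(factors, coefficients, sd = 0, n_center = 5,
                              seed = 1) {
  if (is.numeric(coefficients)) coefficients <- list(Y = coefficients)
  if (any(lengths(coefficients) != 10)) {
    stop("each surface needs exactly 10 coefficients", call. = FALSE)
  }
  if (is.null(names(coefficients))) {
    names(coefficients) <- paste0("Y", seq_along(coefficients))
  }
  sd <- rep_len(sd, length(coefficients))
  set.seed(seed)
  design <- bbd_design(factors, n_center = n_center)
  coded <- code_point(factors, design[, factors$name])
  X <- quad_model_matrix(coded, factors$name)
  for (i in seq_along(coefficients)) {
    design[[names(coefficients)[i]]] <-
      drop(X %*% coefficients[[i]]) + stats::rnorm(nrow(X), 0, sd[i])
  }
  attr(design, "true_coefficients") <- coefficients
  attr(design, "factors") <- factors
  class(design) <- c("bbd_design", "data.frame")
  design
}

# one random sequence of given length
rand_seq <- function(len) {
  paste(sample(names(.residue_mass$average), len, replace = TRUE), collapse = "")
}

#' Simulate a peptide identification table with planted funnel survivors
#'
#' Generates `n` random peptide records of which exactly `n_survivors` are
#' constructed to pass every stage of the screening funnel under `config`;
#' every other record is given at least one disqualifying field (cycling
#' over the six stages). Because the funnel is a conjunction of independent
#' filters, [screen_peptides()] on the generated table returns exactly the
#' planted set, in any record order.
#'
#' @param seed Integer RNG seed.
#' @param n Number of records.
#' @param n_survivors Number of planted survivors (<= n).
#' @param config The [screen_config()] the table should be screened with.
#' @return A list with `records` (data.frame in [read_peptide_table()]
#'   layout, shuffled) and `planted` (the survivor sequences).
#' @export
sim_peptide_table <- function(seed, n = 100, n_survivors = 5,
                              config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  if (n_survivors > n) stop("'n_survivors' must be <= 'n'", call. = FALSE)
  set.seed(seed)

  seqs <- character(0)
  new_seq <- function(len_range, mass_pred) {
    repeat {
      s <- rand_seq(sample(len_range, 1))
      if (!s %in% seqs && mass_pred(peptide_mass(s))) return(s)
    }
  }
  rec <- vector("list", n)
  violations <- c("mass", "alc", "area", "ranker", "toxin", "solubility")
  for (i in seq_len(n)) {
    planted <- i <= n_survivors
    viol <- if (planted) "none" else violations[1 + (i - n_survivors - 1) %% 6]
    s <- if (viol == "mass") {
      new_seq(10:18, function(m) m >= config$max_mass)
    } else {
      new_seq(4:7, function(m) m < config$max_mass)
    }
    seqs <- c(seqs, s)
    rec[[i]] <- data.frame(
      sequence = s,
      mass = peptide_mass(s),
      alc = if (viol == "alc") stats::runif(1, 40, config$min_alc * 0.98)
            else stats::runif(1, config$min_alc * 1.05, 99),
      rt = stats::runif(1, 5, 25),
      area = if (viol == "area") config$min_area * 10^stats::runif(1, -2, -0.1)
             else config$min_area * 10^stats::runif(1, 0.1, 1.5),
      ranker = if (viol == "ranker") stats::runif(1, 0, config$min_bioactivity * 0.9)
               else stats::runif(1, min(config$min_bioactivity * 1.1, 0.99), 1),
      toxin = if (viol == "toxin") "Toxin" else "Non-Toxin",
      solubility = if (viol == "solubility") "poor" else "good",
      stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, rec)
  planted_seqs <- records$sequence[seq_len(n_survivors)]
  records <- records[sample(n), , drop = FALSE]
  rownames(records) <- NULL
  list(records = records, planted = planted_seqs)
}
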