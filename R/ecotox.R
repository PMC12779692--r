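#' Aquatic toxicity, narcosis, bioconcentration and applicability flags
#'
#' ECOSAR-style baseline (narcosis) QSARs estimate aquatic toxicity of
#' neutral organics from the octanol-water partition coefficient alone:
#' \deqn{\log LC_{50} = m \cdot \log K_{ow} + b}
#' with \eqn{LC_{50}} in mmol/L, converted to mg/L via the molecular weight.
#' Classification follows the standard acute/chronic concentration bands;
#' companion quantities are the narcotic activity \eqn{LC_{50}/C_s}, the
#' community hazard concentration HC5, the chronic value (geometric mean of
#' NOEC and LOEC) and the Arnot-Gobas bioconcentration factor.
#'
#' @name ecotox
NULL

TOX_CLASSES <- c("not_harmful", "harmful", "toxic", "very_toxic")

#' Classify an aquatic toxicity concentration
#'
#' Acute bands (LC50/EC50, mg/L): > 100 not harmful; (10, 100] harmful;
#' (1, 10] toxic; (0, 1] very toxic. Chronic bands (ChV, mg/L): > 10 not
#' harmful; (1, 10] harmful; (0.1, 1] toxic; (0, 0.1] very toxic.
#'
#' Two conventions close gaps the printed band table leaves open: boundary
#' concentrations (exactly 1, 10, 100 mg/L) fall in the more-toxic adjacent
#' class (intervals half-open, closed on the toxic side), and chronic values
#' in (10, 100] -- a band the chronic table does not define -- are assigned
#' `not_harmful` with a warning of class `silicotox_chronic_gap`.
#'
#' @param concentration numeric vector of concentrations (mg/L), > 0.
#' @param chronic logical: chronic (ChV) bands instead of acute.
#' @return factor with levels `not_harmful`, `harmful`, `toxic`, `very_toxic`.
#' @export
classify_toxicity <- function(concentration, chronic = FALSE) {
  stopifnot(is.numeric(concentration), is.logical(chronic))
  if (any(!is.finite(concentration)) || any(concentration <= 0))
    stop("concentration must be positive and finite")
  chronic <- rep_len(chronic, length(concentration))

  cls <- character(length(concentration))
  acute <- !chronic
  ca <- concentration[acute]
  cls[acute] <- ifelse(ca > 100, "not_harmful",
                ifelse(ca > 10, "harmful",
                ifelse(ca > 1, "toxic", "very_toxic")))
  cc <- concentration[chronic]
  if (length(cc)) {
    if (any(cc > 10 & cc <= 100)) {
      warning(structure(
        class = c("silicotox_chronic_gap", "warning", "condition"),
        list(message = "chronic value in the undefined (10, 100] band; assigned not_harmful",
             call = sys.call(-1))))
    }
    cls[chronic] <- ifelse(cc > 10, "not_harmful",
                    ifelse(cc > 1, "harmful",
                    ifelse(cc > 0.1, "toxic", "very_toxic")))
  }
  factor(cls, levels = TOX_CLASSES)
}

#' Predict an acute/chronic concentration from log Kow
#'
#' Evaluates \eqn{LC_{50}\,[\mathrm{mmol/L}] = 10^{m \log K_{ow} + b}},
#' converts to mg/L with the molecular weight, classifies the result and
#' sets the applicability flags.
#'
#' @param log_kow octanol-water partition coefficient (dimensionless).
#' @param molecular_weight g/mol, > 0.
#' @param coeff one row of a coefficient set (see [read_qsar_coefficients()]):
#'   a list/data.frame with `endpoint_id`, `m`, `b`, `kow_domain_max` and
#'   optionally `chronic` (default FALSE).
#' @param solubility water solubility (mg/L) used for the
#'   `exceeds_solubility` flag; `NA` leaves the flag `NA`.
#' @return one-row data.frame: `endpoint_id`, `lc50_mmol_l`,
#'   `concentration_mg_l`, `tox_class`, `exceeds_solubility`,
#'   `outside_kow_domain`.
#' @export
predict_lc50 <- function(log_kow, molecular_weight, coeff, solubility = NA_real_) {
  stopifnot(is.numeric(log_kow), length(log_kow) == 1L,
            is.numeric(molecular_weight), length(molecular_weight) == 1L)
  if (molecular_weight <= 0) stop("molecular_weight must be positive")
  need <- c("endpoint_id", "m", "b", "kow_domain_max")
  miss <- setdiff(need, names(coeff))
  if (length(miss))
    stop("QSAR coefficient set missing fields: ", paste(miss, collapse = ", "))
  chronic <- isTRUE(coeff$chronic)

  lc50_mmol <- 10^(coeff$m * log_kow + coeff$b)
  conc <- lc50_mmol * molecular_weight
  data.frame(
    endpoint_id = coeff$endpoint_id,
    lc50_mmol_l = lc50_mmol,
    concentration_mg_l = conc,
    tox_class = classify_toxicity(conc, chronic = chronic),
    exceeds_solubility = if (is.na(solubility)) NA else conc > solubility,
    outside_kow_domain = log_kow > coeff$kow_domain_max,
    stringsAsFactors = FALSE
  )
}

#' Narcotic (baseline toxicity) chemical activity
#'
#' The activity of a narcotic toxicant is approximated by the ratio of the
#' concentration needed to induce narcosis (taken as the LC50) to the
#' compound's water solubility. Ratios above 1 mean the nominal effect
#' concentration exceeds solubility, so the narcosis prediction is
#' unreliable (supersaturation).
#'
#' @param lc50 effect concentration (mg/L).
#' @param solubility water solubility (mg/L), > 0.
#' @return list with `activity` (dimensionless) and logical `supersaturated`.
#' @export
narcosis_activity <- function(lc50, solubility) {
  stopifnot(is.numeric(lc50), is.numeric(solubility))
  if (any(!is.finite(solubility)) || any(solubility <= 0))
    stop("solubility must be positive")
  a <- lc50 / solubility
  list(activity = a, supersaturated = a > 1)
}

#' Hazardous concentration for 5\% of aquatic communities
#'
#' \deqn{\log(1/HC_5) = -4.52 + 1.05 \cdot \log K_{ow}} so
#' \eqn{HC_5 = 10^{-(-4.52 + 1.05 \log K_{ow})}} in \eqn{\mu}mol/L.
#'
#' @param log_kow numeric vector.
#' @return HC5 in micromol/L.
#' @export
hc5 <- function(log_kow) {
  stopifnot(is.numeric(log_kow))
  10^(-(-4.52 + 1.05 * log_kow))
}

#' Chronic value from NOEC and LOEC
#'
#' Geometric mean \eqn{\sqrt{NOEC \cdot LOEC}} of the no-observed and
#' lowest-observed effect concentrations, returned in the input unit (mg/L).
#'
#' @param noec,loec positive concentrations (mg/L).
#' @return chronic value (mg/L).
#' @export
chronic_value <- function(noec, loec) {
  stopifnot(is.numeric(noec), is.numeric(loec))
  if (any(noec <= 0) || any(loec <= 0))
    stop("NOEC and LOEC must be positive")
  10^((log10(noec) + log10(loec)) / 2)
}

#' Arnot-Gobas bioconcentration factor
#'
#' \deqn{BCF = (1 - L_B) + \frac{k_1 \phi}{k_2 + k_E + k_G + k_M}}
#' where \eqn{1 - L_B} is the non-lipid organism fraction term, \eqn{k_1}
#' the respiratory uptake rate (L/kg/day), \eqn{k_2, k_E, k_G, k_M} the
#' respiratory, fecal-egestion, growth-dilution and metabolic elimination
#' rates (1/day), and \eqn{\phi} the bioavailable (freely dissolved)
#' fraction. Compounds with BCF at or above `bioaccumulation_threshold`
#' (default 5000 L/kg) are flagged bioaccumulative.
#'
#' @param l_b lipid-related organism fraction \eqn{L_B} in [0, 1).
#' @param k1 uptake rate constant (L/kg/day), >= 0.
#' @param k2,kE,kG,kM elimination rate constants (1/day), >= 0, with a
#'   strictly positive sum.
#' @param phi bioavailable fraction in [0, 1].
#' @param bioaccumulation_threshold L/kg (default 5000).
#' @return list with `bcf` (L/kg) and logical `bioaccumulative`.
#' @export
bcf <- function(l_b, k1, k2, kE = 0, kG = 0, kM = 0, phi = 1,
                bioaccumulation_threshold = 5000) {
  stopifnot(is.numeric(l_b), is.numeric(k1), is.numeric(phi))
  if (any(phi < 0 | phi > 1)) stop("phi must lie in [0, 1]")
  denom <- k2 + kE + kG + kM
  if (any(denom <= 0)) stop("elimination rate sum k2 + kE + kG + kM must be positive")
  val <- (1 - l_b) + (k1 * phi) / denom
  list(bcf = val, bioaccumulative = val >= bioaccumulation_threshold)
}

#' Lipophilicity and QSAR applicability-domain flags
#'
#' A compound is flagged lipophilic when log Kow exceeds 3 (strict), and
#' outside the fish / Daphnia magna narcosis-QSAR applicability domain when
#' log Kow exceeds 5.0 (strict).
#'
#' @param log_kow numeric vector.
#' @param lipophilic_threshold default 3.
#' @param domain_max default 5.0.
#' @return data.frame with `log_kow`, `lipophilic`,
#'   `outside_fish_daphnia_domain`.
#' @export
lipophilicity_flags <- function(log_kow, lipophilic_threshold = 3, domain_max = 5.0) {
  stopifnot(is.numeric(log_kow))
  data.frame(
    log_kow = log_kow,
    lipophilic = log_kow > lipophilic_threshold,
    outside_fish_daphnia_domain = log_kow > domain_max
  )
}

#' Read a QSAR coefficient configuration
#'
#' YAML file keyed by endpoint id, each entry holding `m`, `b`,
#' `kow_domain_max` and optionally `chronic`. The package ships an editable
#' default at `system.file("extdata", "qsar_coefficients.yaml",
#' package = "silicotox")` whose slope/intercept values are generic
#' neutral-organic narcosis placeholders meant to be replaced with the
#' coefficient set of the QSAR suite in use.
#'
#' @param path YAML file; defaults to the shipped configuration.
#' @return named list of coefficient rows, each with `endpoint_id` added.
#' @export
read_qsar_coefficients <- function(path = system.file("extdata",
                                                      "qsar_coefficients.yaml",
                                                      package = "silicotox")) {
  cfg <- yaml::read_yaml(path)
  if (!length(cfg)) stop("no endpoints defined in ", path)
  out <- lapply(names(cfg), function(id) {
    cf <- cfg[[id]]
    miss <- setdiff(c("m", "b", "kow_domain_max"), names(cf))
    if (length(miss))
      stop("endpoint '", id, "' missing fields: ", paste(miss, collapse = ", "))
    cf$endpoint_id <- id
    if (is.null(cf$chronic)) cf$chronic <- FALSE
    cf
  })
  names(out) <- names(cfg)
  out
}
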