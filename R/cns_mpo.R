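#' CNS multiparameter optimization (MPO) desirability score
#'
#' The CNS MPO score aggregates six physicochemical attributes --
#' lipophilicity (logP, here adapted to log Kow), distribution coefficient
#' logD, topological polar surface area (TPSA), most basic pKa, molecular
#' weight and H-bond donor count -- through piecewise-linear desirability
#' functions \eqn{T_k(x) \in [0, 1]} and sums the weighted values:
#' \deqn{MPO = \sum_{k=1}^{6} w_k T_k(x_k), \qquad w_k \in [0, 1].}
#' With unit weights the score ranges from 0 (low CNS desirability) to 6.
#'
#' Each monotone attribute is fully desirable up to its ideal bound, falls
#' linearly to 0 at a cutoff, and is 0 beyond; TPSA is hump-shaped, fully
#' desirable inside an ideal window with linear ramps to outer cutoffs.
#'
#' @name cns_mpo
NULL

#' Default CNS MPO desirability specifications
#'
#' Ideal bounds: log Kow <= 3, logD <= 2, 40 < TPSA <= 90 A^2, pKa <= 8,
#' MW <= 500 g/mol, HBD <= 1. Ramp cutoffs follow the conventional
#' desirability-function defaults (logP 5, logD 4, TPSA outer bounds 20 and
#' 120, pKa 10, MW 800, HBD 3.5); all bounds and weights are editable, and a
#' YAML override can be loaded with [read_mpo_specs()].
#'
#' @return named list of six specs; each spec is a list with `attribute`,
#'   `shape` ("monotone_decreasing" or "hump"), ideal/cutoff bounds and
#'   `weight`.
#' @export
default_mpo_specs <- function() {
  list(
    log_kow = list(attribute = "log_kow", shape = "monotone_decreasing",
                   ideal = 3, cutoff = 5, weight = 1),
    log_d = list(attribute = "log_d", shape = "monotone_decreasing",
                 ideal = 2, cutoff = 4, weight = 1),
    tpsa = list(attribute = "tpsa", shape = "hump",
                ideal_low = 40, ideal_high = 90,
                cutoff_low = 20, cutoff_high = 120, weight = 1),
    pka = list(attribute = "pka", shape = "monotone_decreasing",
               ideal = 8, cutoff = 10, weight = 1),
    molecular_weight = list(attribute = "molecular_weight",
                            shape = "monotone_decreasing",
                            ideal = 500, cutoff = 800, weight = 1),
    hbd_count = list(attribute = "hbd_count", shape = "monotone_decreasing",
                     ideal = 1, cutoff = 3.5, weight = 1)
  )
}

validate_mpo_spec <- function(spec) {
  if (is.null(spec$shape)) stop("desirability spec needs a shape")
  if (spec$shape == "monotone_decreasing") {
    if (!(spec$cutoff > spec$ideal))
      stop("malformed spec '", spec$attribute,
           "': cutoff must lie strictly beyond the ideal bound")
  } else if (spec$shape == "hump") {
    if (!(spec$cutoff_low < spec$ideal_low &&
          spec$ideal_low < spec$ideal_high &&
          spec$ideal_high < spec$cutoff_high))
      stop("malformed hump spec '", spec$attribute,
           "': need cutoff_low < ideal_low < ideal_high < cutoff_high")
  } else stop("unknown desirability shape: ", spec$shape)
  w <- spec$weight %||% 1
  if (!is.numeric(w) || w < 0 || w > 1)
    stop("weight must lie in [0, 1]")
  invisible(spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Piecewise-linear desirability of one attribute value
#'
#' Monotone-decreasing attributes score 1 up to the ideal bound, ramp
#' linearly to 0 at the cutoff, and 0 beyond. Hump attributes score 1
#' inside the ideal window (half-open: `(ideal_low, ideal_high]`), ramp to 0
#' at the outer cutoffs.
#'
#' @param x numeric attribute value(s).
#' @param spec a single spec from [default_mpo_specs()] (weight ignored
#'   here; applied in [score_cns_mpo()]).
#' @return desirability in [0, 1].
#' @export
desirability <- function(x, spec) {
  validate_mpo_spec(spec)
  stopifnot(is.numeric(x))
  if (spec$shape == "monotone_decreasing") {
    d <- (spec$cutoff - x) / (spec$cutoff - spec$ideal)
  } else {
    d <- ifelse(x <= spec$ideal_low,
                (x - spec$cutoff_low) / (spec$ideal_low - spec$cutoff_low),
                (spec$cutoff_high - x) / (spec$cutoff_high - spec$ideal_high))
  }
  pmin(1, pmax(0, d))
}

#' Score the six-attribute CNS MPO desirability
#'
#' @param attrs named list or one-row data.frame with `log_kow`, `log_d`,
#'   `tpsa`, `pka`, `molecular_weight`, `hbd_count`.
#' @param specs list of six desirability specs (default
#'   [default_mpo_specs()]).
#' @return list with `desirabilities` (named numeric, weighted) and `total`.
#' @examples
#' score_cns_mpo(list(log_kow = 1, log_d = 0, tpsa = 60, pka = 7,
#'                    molecular_weight = 300, hbd_count = 0))$total  # 6
#' @export
score_cns_mpo <- function(attrs, specs = default_mpo_specs()) {
  need <- vapply(specs, function(s) s$attribute, character(1))
  miss <- need[!need %in% names(attrs)]
  if (length(miss))
    stop("missing MPO attribute(s): ", paste(miss, collapse = ", "))
  d <- vapply(specs, function(s) {
    x <- attrs[[s$attribute]]
    if (is.null(x) || is.na(x)) stop("missing MPO attribute: ", s$attribute)
    (s$weight %||% 1) * desirability(x, s)
  }, numeric(1))
  names(d) <- need
  list(desirabilities = d, total = sum(d))
}

#' Score a compound table
#'
#' @param df data.frame with one row per compound, a `compound_id` column
#'   and the six attribute columns.
#' @param specs desirability specs.
#' @return data.frame of per-attribute desirabilities plus `mpo_total`.
#' @export
score_cns_mpo_table <- function(df, specs = default_mpo_specs()) {
  rows <- lapply(seq_len(nrow(df)), function(i) {
    sc <- score_cns_mpo(as.list(df[i, ]), specs)
    c(as.list(sc$desirabilities), mpo_total = sc$total)
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  names(out)[seq_along(specs)] <- paste0("d_", names(rows[[1]])[seq_along(specs)])
  cbind(compound_id = df$compound_id, out)
}

#' Read CNS MPO desirability specs from YAML
#'
#' The file mirrors the structure of [default_mpo_specs()]: one entry per
#' attribute with `shape`, bounds and `weight`; omitted attributes keep
#' their defaults.
#'
#' @param path YAML file.
#' @return validated list of specs.
#' @export
read_mpo_specs <- function(path) {
  user <- yaml::read_yaml(path)
  specs <- default_mpo_specs()
  for (nm in names(user)) {
    spec <- utils::modifyList(specs[[nm]] %||% list(attribute = nm), user[[nm]])
    specs[[nm]] <- spec
  }
  lapply(specs, validate_mpo_spec)
  specs
}
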