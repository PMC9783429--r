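#' Trait specification: transform and unit-adjustment rules
#'
#' Encodes how each trait is carried to the analysis scale and which
#' nuisance term absorbs unit-level variation:
#' * `preference` (eggs laid in a multi-medium choice arena): response is
#'   `log(eggs + offset)`; arena enters the model as a fixed block.
#' * `fecundity` (eggs laid in a single-medium no-choice vial): response is
#'   `log(eggs + offset)`; no unit term.
#' * `performance` (egg-to-adult survival): response is
#'   `asin(sqrt(adults / eggs))` with the proportion capped at 1; the unit
#'   term is replaced by the log egg-density covariate `log(eggs + offset)`.
#'
#' @param trait One of `"preference"`, `"fecundity"`, `"performance"`.
#' @param offset Offset added inside the log for count responses and for
#'   the egg-density covariate. Zero counts occur in choice and no-choice
#'   assays, so the conventional `log(x + 1)` is the default.
#' @param survival_cap Cap egg-to-adult survival at 1 when more adults than
#'   eggs were counted (miscounted low-egg vials); capped records are
#'   retained and flagged.
#' @return A list of class `sa_trait_spec`.
#' @export
trait_spec <- function(trait = c("preference", "fecundity", "performance"),
                       offset = 1, survival_cap = TRUE) {
  trait <- match.arg(trait)
  if (!is.numeric(offset) || length(offset) != 1 || offset <= 0) {
    sa_abort_value("offset must be a single positive number")
  }
  structure(
    list(
      trait = trait,
      transform = if (trait == "performance") "arcsine_sqrt_proportion" else "log_count",
      unit_adjustment = switch(trait,
        preference = "arena_block",
        fecundity = "none",
        performance = "log_egg_density"
      ),
      offset = offset,
      survival_cap = isTRUE(survival_cap)
    ),
    class = "sa_trait_spec"
  )
}

as_trait_spec <- function(spec) {
  if (inherits(spec, "sa_trait_spec")) spec else trait_spec(spec)
}

#' Transform raw counts to the analysis scale
#'
#' Appends a `response` column (and, for performance, a `capped` flag) to an
#' observation table. Count traits use `log(eggs + offset)`; performance uses
#' the angular transform `asin(sqrt(p))` of the egg-to-adult proportion
#' `p = adults / eggs`, capped at 1 when `adults > eggs`. Performance records
#' with `eggs = 0` have an undefined proportion and are excluded with a
#' warning. Tables that already carry a `response` column (e.g. Gaussian
#' synthetic data) are returned unchanged.
#'
#' @param data An observation tibble.
#' @param spec A trait name or [trait_spec()] object.
#' @return The table with `response` (and `capped`) columns appended.
#' @examples
#' obs <- generate_dataset(sim_config(family = "poisson", mu = log(20),
#'                                    pops_per_env = c(2, 2, 2), seed = 1))
#' transform_response(obs, "fecundity")
#' @export
transform_response <- function(data, spec) {
  spec <- as_trait_spec(spec)
  if ("response" %in% names(data)) {
    return(data)
  }
  if (spec$trait == "performance") {
    if (!("adults" %in% names(data)) || anyNA(data$adults)) {
      sa_abort_schema("performance trait requires a complete 'adults' column")
    }
    drop <- data$eggs == 0
    if (any(drop)) {
      rlang::warn(paste0("excluding ", sum(drop),
                         " performance record(s) with eggs = 0 (undefined proportion)"))
      data <- data[!drop, , drop = FALSE]
    }
    p <- data$adults / data$eggs
    capped <- p > 1
    if (any(capped) && !spec$survival_cap) {
      sa_abort_value("adults > eggs encountered with survival_cap = FALSE")
    }
    p[capped] <- 1
    data$response <- asin(sqrt(p))
    data$capped <- capped
  } else {
    if ("adults" %in% names(data) && any(!is.na(data$adults))) {
      sa_abort_schema(paste0("adults column present for trait '", spec$trait,
                             "'; adults are only used for performance"))
    }
    data$adults <- NULL
    data$response <- log(data$eggs + spec$offset)
  }
  data
}
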