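## Synthetic species-parameter tables with the statistical structure the
## curation pipeline assumes: correlated, heavy-tailed positive marginals for
## (assimilation, conductance), an allocation fraction biased towards a high
## default value, lifespans and completeness scores spanning the filter
## thresholds, and optionally planted outliers with recorded identities.

#' Specification of a synthetic species table
#'
#' Parameters of the generator. Assimilation and conductance are drawn
#' jointly log-normal (heavy-tailed on the positive axis, clumped joint
#' distribution) with correlation `log_cor` between the log-parameters. The
#' allocation fraction is a mixture: with probability `kappa_default_weight`
#' the conventional default value `kappa_default` (collections are biased
#' towards high allocation because reproduction data are scarce), otherwise
#' a Beta draw. Lifespan is log-normal with a tail crossing the 100-year
#' filter bound; completeness is drawn on the 0-10 half-point scale with
#' most mass between 1 and 6. `n_outliers` rows are planted far outside the
#' interquartile fences by scaling one of the two joint parameters, and
#' their identities are recorded as ground truth.
#'
#' @param n_species number of rows (>= 0).
#' @param seed integer seed governing all randomness of the draw.
#' @param log_pAm_mean,log_pAm_sd mean and sd of `log(p_Am_max)`.
#' @param log_v_mean,log_v_sd mean and sd of `log(v_dot)`.
#' @param log_cor correlation between the two log-parameters, in (-1, 1).
#' @param kappa_default,kappa_default_weight point-mass component of the
#'   allocation mixture.
#' @param kappa_shape1,kappa_shape2 Beta parameters of the spread component.
#' @param lifespan_meanlog,lifespan_sdlog log-normal lifespan (years).
#' @param p_M_meanlog,p_M_sdlog log-normal somatic maintenance.
#' @param completeness_mean,completeness_sd location/spread of the
#'   completeness scores before rounding to the half-point grid.
#' @param frac_std fraction of rows labelled with the standard model;
#'   remaining rows get other model-type labels.
#' @param n_outliers number of planted extreme rows.
#' @param outlier_factor multiplicative displacement of planted outliers.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_species = 300, seed = 1,
                       log_pAm_mean = log(600), log_pAm_sd = 1.1,
                       log_v_mean = log(0.025), log_v_sd = 0.7,
                       log_cor = 0.5,
                       kappa_default = 0.8, kappa_default_weight = 0.6,
                       kappa_shape1 = 5, kappa_shape2 = 2,
                       lifespan_meanlog = log(8), lifespan_sdlog = 1.2,
                       p_M_meanlog = log(50), p_M_sdlog = 1,
                       completeness_mean = 3, completeness_sd = 1.5,
                       frac_std = 0.85, n_outliers = 0,
                       outlier_factor = 50) {
  if (!is.numeric(n_species) || n_species < 0)
    stop("'n_species' must be >= 0", call. = FALSE)
  if (abs(log_cor) >= 1)
    stop("'log_cor' must lie strictly in (-1, 1)", call. = FALSE)
  if (log_pAm_sd <= 0 || log_v_sd <= 0 || lifespan_sdlog <= 0 || p_M_sdlog <= 0)
    stop("scale parameters must be positive", call. = FALSE)
  if (kappa_default <= 0 || kappa_default >= 1 ||
      kappa_default_weight < 0 || kappa_default_weight > 1)
    stop("invalid kappa mixture specification", call. = FALSE)
  if (frac_std < 0 || frac_std > 1)
    stop("'frac_std' must lie in [0, 1]", call. = FALSE)
  if (n_outliers < 0 || n_outliers > n_species)
    stop("'n_outliers' must lie in [0, n_species]", call. = FALSE)
  if (outlier_factor <= 1)
    stop("'outlier_factor' must exceed 1", call. = FALSE)
  spec <- as.list(environment())
  class(spec) <- "synth_spec"
  spec
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic species table
#'
#' Draws a table deterministically from a [synth_spec()]: the same spec and
#' seed always produce the identical table. Alongside the table, the ground
#' truth records which rows were planted as outliers and which rows fail
#' the model-type / lifespan / completeness filter, so that curation tests
#' can check exact recovery.
#'
#' @param spec a [synth_spec()] object.
#' @return List with `table` (data frame with columns `species_id`,
#'   `model_type`, `lifespan_y`, `completeness`, `p_Am_max`, `v_dot`,
#'   `kappa`, `p_M_vol`) and `ground_truth` (list with `outlier_ids` and
#'   `filter_fail_ids`).
#' @export
generate_species_table <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- as.integer(spec$n_species)
  empty <- data.frame(species_id = character(), model_type = character(),
                      lifespan_y = numeric(), completeness = numeric(),
                      p_Am_max = numeric(), v_dot = numeric(),
                      kappa = numeric(), p_M_vol = numeric(),
                      stringsAsFactors = FALSE)
  if (n == 0L)
    return(list(table = empty,
                ground_truth = list(outlier_ids = character(),
                                    filter_fail_ids = character())))
  with_seed(spec$seed, {
    z1 <- stats::rnorm(n)
    z2 <- spec$log_cor * z1 + sqrt(1 - spec$log_cor^2) * stats::rnorm(n)
    pAm <- exp(spec$log_pAm_mean + spec$log_pAm_sd * z1)
    v <- exp(spec$log_v_mean + spec$log_v_sd * z2)
    use_default <- stats::runif(n) < spec$kappa_default_weight
    kappa <- ifelse(use_default, spec$kappa_default,
                    stats::rbeta(n, spec$kappa_shape1, spec$kappa_shape2))
    lifespan <- stats::rlnorm(n, spec$lifespan_meanlog, spec$lifespan_sdlog)
    p_M <- stats::rlnorm(n, spec$p_M_meanlog, spec$p_M_sdlog)
    completeness <- round(2 * pmin(pmax(
      stats::rnorm(n, spec$completeness_mean, spec$completeness_sd), 0), 10)) / 2
    model_type <- ifelse(stats::runif(n) < spec$frac_std, "std",
                         sample(c("abj", "stf", "stx"), n, replace = TRUE))
    ids <- sprintf("syn%04d", seq_len(n))

    outlier_ids <- character()
    if (spec$n_outliers > 0L) {
      pick <- sample.int(n, spec$n_outliers)
      for (j in seq_along(pick)) {
        i <- pick[j]
        if (j %% 2L == 1L) pAm[i] <- pAm[i] * spec$outlier_factor
        else v[i] <- v[i] * spec$outlier_factor
        model_type[i] <- "std"
        lifespan[i] <- min(lifespan[i], 50)
        completeness[i] <- max(completeness[i], 3)
      }
      outlier_ids <- ids[sort(pick)]
    }

    table <- data.frame(species_id = ids, model_type = model_type,
                        lifespan_y = lifespan, completeness = completeness,
                        p_Am_max = pAm, v_dot = v, kappa = kappa,
                        p_M_vol = p_M, stringsAsFactors = FALSE)
    fail <- table$model_type != "std" | table$lifespan_y >= 100 |
      table$completeness < 2.5
    list(table = table,
         ground_truth = list(outlier_ids = outlier_ids,
                             filter_fail_ids = ids[fail]))
  })
}

#' The bundled synthetic species table
#'
#' A frozen 300-row synthetic table shipped with the package (generated once
#' with `synth_spec(n_species = 300, seed = 20200301, n_outliers = 6)` and
#' stored as CSV), used as a stable regression fixture for the curation
#' pipeline.
#'
#' @return The species table as a data frame.
#' @export
bundled_fixture <- function() {
  path <- system.file("extdata", "synthetic_amp_species.csv",
                      package = "debsim", mustWork = TRUE)
  read_species_table(path)
}
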