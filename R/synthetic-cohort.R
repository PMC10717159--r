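# Synthetic per-animal cohort tables with known per-condition effect
# structure, for validating the group-comparison statistics end to end.

#' Specification of a synthetic cohort
#'
#' Describes a set of experimental conditions (genotype, febuxostat dose,
#' uric-acid dose, day after synchronization) and, for each measurement
#' endpoint, a per-condition normal mean/SD effect model. Endpoints marked
#' non-negative are truncated at 0; count endpoints are additionally
#' rounded to integers.
#'
#' @param conditions data frame with columns `condition` (unique label),
#'   `genotype`, `fbx_dose_ug_ml`, `ua_dose_mM`, `day`.
#' @param endpoints named list; each element is a list with `mean` and `sd`
#'   numeric vectors (length = number of conditions, recycled if length 1)
#'   and optional logicals `nonneg` and `integer`.
#' @param n_animals_per_condition animals per condition (default 30, the
#'   assay's per-condition minimum).
#' @param seed integer seed.
#' @return An object of class `wt_cohort_spec`.
#' @export
cohort_spec <- function(conditions, endpoints, n_animals_per_condition = 30L,
                        seed = 1L) {
  stopifnot(is.data.frame(conditions), nrow(conditions) >= 1L)
  need <- c("condition", "genotype", "fbx_dose_ug_ml", "ua_dose_mM", "day")
  missing_cols <- setdiff(need, names(conditions))
  if (length(missing_cols))
    stop("`conditions` lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(conditions$condition))
    stop("condition labels must be unique", call. = FALSE)
  if (n_animals_per_condition < 1L)
    stop("`n_animals_per_condition` must be >= 1", call. = FALSE)
  k <- nrow(conditions)
  stopifnot(is.list(endpoints), length(endpoints) >= 1L, !is.null(names(endpoints)))
  endpoints <- lapply(endpoints, function(e) {
    e$mean <- rep_len(e$mean, k)
    e$sd <- rep_len(e$sd, k)
    if (any(e$sd < 0)) stop("endpoint SDs must be >= 0", call. = FALSE)
    e$nonneg <- isTRUE(e$nonneg)
    e$integer <- isTRUE(e$integer)
    e
  })
  structure(list(conditions = conditions, endpoints = endpoints,
                 n_animals_per_condition = as.integer(n_animals_per_condition),
                 seed = seed),
            class = "wt_cohort_spec")
}

#' Generate a per-animal cohort table with ground truth
#'
#' Draws every animal x endpoint value from the condition's normal effect
#' model (truncating and rounding as declared), in a fixed deterministic
#' order, so identical specs give identical tables.
#'
#' @param spec a [cohort_spec()].
#' @return A list: `table`, a long data frame with columns `animal_id`,
#'   `condition`, `genotype`, `fbx_dose_ug_ml`, `ua_dose_mM`, `day`,
#'   `endpoint`, `value`; and `truth`, a data frame of the true
#'   per-condition means and SDs.
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "wt_cohort_spec"))
  n <- spec$n_animals_per_condition
  conds <- spec$conditions
  with_seed(spec$seed, {
    blocks <- list()
    truth <- list()
    for (i in seq_len(nrow(conds))) {
      for (ep in names(spec$endpoints)) {
        e <- spec$endpoints[[ep]]
        v <- rnorm(n, e$mean[i], e$sd[i])
        if (e$nonneg) v <- pmax(v, 0)
        if (e$integer) v <- round(v)
        blocks[[length(blocks) + 1L]] <- data.frame(
          animal_id = sprintf("%s_%02d", conds$condition[i], seq_len(n)),
          condition = conds$condition[i],
          genotype = conds$genotype[i],
          fbx_dose_ug_ml = conds$fbx_dose_ug_ml[i],
          ua_dose_mM = conds$ua_dose_mM[i],
          day = conds$day[i],
          endpoint = ep,
          value = v)
        truth[[length(truth) + 1L]] <- data.frame(
          condition = conds$condition[i], endpoint = ep,
          true_mean = e$mean[i], true_sd = e$sd[i])
      }
    }
    list(table = do.call(rbind, blocks), truth = do.call(rbind, truth))
  })
}

#' Built-in cohort presets
#'
#' Effect models encoding the qualitative phenotype structure the package's
#' assays are designed to resolve. Because no per-animal source tables are
#' published for these assays, presets are calibrated to standardized
#' effect sizes (Cohen's d) on arbitrary but realistic scales, not to raw
#' published units:
#'
#' * `"contractility"` — two genotypes at day 4: the dystrophin;twitchin
#'   double mutant contracts more weakly than the twitchin single mutant
#'   (`amplitude_px2`: d = 5 deficit) at identical contraction frequency
#'   (`frequency_hz`: no difference).
#' * `"rescue"` — movement-trace areas at day 12 with dose-ordered rescue:
#'   untreated double mutant = untreated single mutant < FBX 5 < FBX 40 <
#'   FBX 40 + UA 2 mM, with prednisone indistinguishable from untreated.
#' * `"nuclei"` — GFP-labelled muscle nuclei per bundle at day 12:
#'   reduced in the mutant, partially restored dose-dependently by FBX.
#' * `"null"` — three identically distributed conditions (type-I-error
#'   studies).
#'
#' @param name preset name.
#' @param n_animals_per_condition animals per condition (default 30).
#' @param seed integer seed.
#' @return A [cohort_spec()].
#' @export
cohort_preset <- function(name = c("contractility", "rescue", "nuclei", "null"),
                          n_animals_per_condition = 30L, seed = 1L) {
  name <- match.arg(name)
  cond <- function(condition, genotype, fbx = 0, ua = 0, day = 4)
    data.frame(condition = condition, genotype = genotype,
               fbx_dose_ug_ml = fbx, ua_dose_mM = ua, day = day)
  spec <- switch(name,
    contractility = cohort_spec(
      rbind(cond("unc-22", "unc-22(e66)"),
            cond("dys-1;unc-22", "dys-1(tm4402);unc-22(e66)")),
      endpoints = list(
        amplitude_px2 = list(mean = c(2.0, 1.0), sd = 0.2, nonneg = TRUE),
        frequency_hz = list(mean = c(2.0, 2.0), sd = 0.25, nonneg = TRUE)),
      n_animals_per_condition, seed),
    rescue = cohort_spec(
      rbind(cond("unc-22 untreated", "unc-22(e66)", day = 12),
            cond("dys-1;unc-22 untreated", "dys-1(tm4402);unc-22(e66)", day = 12),
            cond("dys-1;unc-22 FBX5", "dys-1(tm4402);unc-22(e66)", fbx = 5, day = 12),
            cond("dys-1;unc-22 FBX40", "dys-1(tm4402);unc-22(e66)", fbx = 40, day = 12),
            cond("dys-1;unc-22 FBX40+UA2", "dys-1(tm4402);unc-22(e66)",
                 fbx = 40, ua = 2, day = 12),
            cond("dys-1;unc-22 prednisone", "dys-1(tm4402);unc-22(e66)", day = 12)),
      endpoints = list(
        trace_area_px2 = list(mean = c(5000, 5000, 7000, 8000, 10000, 5200),
                              sd = 1500, nonneg = TRUE)),
      n_animals_per_condition, seed),
    nuclei = cohort_spec(
      rbind(cond("wild type", "N2 (ccIs4251)", day = 12),
            cond("dys-1", "dys-1(tm4402);ccIs4251", day = 12),
            cond("dys-1 FBX5", "dys-1(tm4402);ccIs4251", fbx = 5, day = 12),
            cond("dys-1 FBX10", "dys-1(tm4402);ccIs4251", fbx = 10, day = 12)),
      endpoints = list(
        nuclei_count = list(mean = c(20, 14, 17, 18), sd = 2,
                            nonneg = TRUE, integer = TRUE)),
      n_animals_per_condition, seed),
    null = cohort_spec(
      rbind(cond("group A", "unc-22(e66)"),
            cond("group B", "unc-22(e66)"),
            cond("group C", "unc-22(e66)")),
      endpoints = list(
        amplitude_px2 = list(mean = 2.0, sd = 0.2, nonneg = TRUE)),
      n_animals_per_condition, seed))
  spec
}
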