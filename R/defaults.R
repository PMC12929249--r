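# Default generator world: a six-class cohort whose class mix, per-class
# indicator prevalences, age structure, loss-to-follow-up rates and
# viral-load detection rates follow the published per-class summary tables
# of the urban HIV-clinic cohort this package emulates (849 patients,
# ~4,316 visits, classes of size 874/804/670/511/758/699).

.default_class_sizes <- c(874, 804, 670, 511, 758, 699)

# per-class prevalence (percent) of each indicator; columns = classes 1..6
.default_indicator_pct <- function() {
  m <- rbind(
    dx_cancer                = c(6.6, 1.2, 6.4, 10.0, 8.4, 12.7),
    dx_cardiovascular        = c(16.6, 3.5, 4.0, 9.4, 9.5, 12.6),
    dx_diabetes              = c(8.1, 1.9, 3.7, 2.7, 2.9, 10.2),
    dx_pulmonary             = c(6.1, 0.4, 5.2, 3.7, 0.7, 2.4),
    dx_hypertension          = c(31.4, 9.6, 27.3, 21.9, 21.1, 37.9),
    dx_kidney_disease        = c(6.4, 4.5, 6.1, 1.0, 6.3, 9.4),
    dx_liver_disease         = c(6.4, 0, 8.2, 10.2, 4.0, 23.6),
    dx_pregnancy             = c(1.1, 0, 10.3, 0, 7.9, 0),
    dx_obesity               = c(8.2, 4.2, 12.4, 6.1, 14.9, 8.7),
    dx_anxiety               = c(8.2, 3.6, 3.6, 9.8, 2.4, 4.1),
    dx_mood_disorders        = c(6.6, 7.3, 9.6, 7.6, 9.5, 2.1),
    dx_personality_disorders = c(0, 0, 0.1, 0, 0.3, 0),
    dx_psychosis             = c(3.1, 1.7, 1.0, 2.7, 2.4, 1.1),
    dx_sud_alcohol           = c(2.3, 2.4, 0.9, 0.4, 2.5, 0.9),
    dx_sud_tobacco           = c(5.4, 2.7, 8.1, 2.3, 8.8, 5.9),
    dx_sud_opioid            = c(2.5, 0, 0.6, 0, 0, 0.3),
    dx_sud_cannabis          = c(0, 1.2, 2.1, 0.2, 0.4, 1.6),
    dx_sud_stimulants        = c(0.9, 1.6, 0.4, 0.4, 1.8, 0.1),
    dx_hepatitis_b           = c(2.9, 0, 1.2, 4.7, 3.6, 13.4),
    dx_hepatitis_c           = c(3.3, 0, 7.2, 5.1, 0.4, 8.9),
    dx_chlamydia             = c(0, 1.5, 0.1, 0.4, 0, 0),
    dx_gonorrhea             = c(1.0, 1.4, 0, 1.0, 0.1, 0.1),
    dx_syphilis              = c(7.7, 14.6, 4.0, 10.4, 12.1, 8.2),
    sh_sexually_active       = c(20.6, 0, 0, 0, 71.9, 0),
    sh_female_partner        = c(18.6, 0, 0, 0, 9.6, 0),
    sh_male_partner          = c(0.5, 0, 0, 0, 97.2, 0),
    sh_uses_condom           = c(8.0, 0, 0, 0, 40.5, 0),
    sh_alcohol               = c(37.2, 0, 0, 0, 46.4, 0),
    sh_tobacco               = c(30.8, 0, 0, 0, 28.4, 0),
    sh_illicit_drugs         = c(22.4, 0, 0, 0, 26.0, 0),
    sh_iv_drugs              = c(0.5, 0, 0, 0, 0, 0),
    lab_gonorrhea            = c(0.9, 4.5, 0.4, 1.8, 0.8, 0),
    lab_chlamydia            = c(1.0, 4.1, 0.6, 1.6, 1.1, 0),
    lab_syphilis             = c(9.3, 24.5, 3.4, 17.4, 8.3, 6.2),
    lab_trichomoniasis       = c(0.7, 0.1, 1.8, 0, 1.7, 0),
    opportunistic_infection  = c(24.1, 26.1, 32.8, 26.6, 27.0, 31.2),
    comorbidities            = c(65.2, 69.7, 56.6, 66.1, 63.1, 71.4),
    poor_adherence           = c(1.1, 0.9, 1.0, 0.2, 0.5, 0.4),
    good_adherence           = c(14.9, 10.9, 17.5, 18.0, 28.5, 24.9),
    sexual_gender_minorities = c(14.9, 50.1, 1.0, 39.7, 17.7, 19.7),
    heterosexual             = c(21.5, 12.1, 25.1, 11.5, 12.9, 10.4),
    life_stressors           = c(42.4, 45.9, 39.9, 38.2, 38.4, 35.8),
    mental_illness           = c(50.9, 51.5, 53.3, 53.4, 51.6, 36.5),
    pregnancy                = c(5.0, 0.2, 24.5, 0.2, 19.8, 0),
    preventive_health        = c(83.2, 83.2, 89.6, 87.1, 85.1, 76.3),
    sti                      = c(41.1, 50.5, 49.6, 40.5, 52.6, 29.0),
    substance_use_disorder   = c(22.2, 30.8, 19.9, 13.9, 23.9, 20.9))
  colnames(m) <- paste0("class", 1:6)
  m
}

# per-class age-bin distribution (percent of class); rows = five age bins
.default_age_pct <- function() {
  m <- rbind(c(7.9, 23.0, 9.9, 6.7, 6.2, 0),
             c(23.1, 53.2, 23.1, 13.7, 34.4, 2.9),
             c(11.7, 8.5, 16.6, 17.2, 17.4, 18.0),
             c(20.8, 10.9, 22.8, 27.2, 24.5, 31.5),
             c(36.5, 4.4, 27.6, 35.2, 17.4, 47.6))
  rownames(m) <- age_bin_levels()
  m
}

#' Default generator configuration
#'
#' The default world is a six-class cohort mirroring the published per-class
#' summary tables: class mix proportional to the six reported class sizes,
#' class-conditional indicator prevalences equal to the printed per-class
#' percentages (23 diagnosis, 8 social-history, 4 laboratory and 12
#' note-topic indicators), age-bin distributions per class, long-gap
#' (loss-to-follow-up) probabilities equal to the reported per-class primary
#' LTFU rates, and viral-load detection probabilities equal to the reported
#' per-class high-viral-load rates. The study window is 2017-01-01 to
#' 2020-12-31.
#'
#' @param n_patients Cohort size (default 849).
#' @param seed Integer RNG seed (default 1).
#' @param negation_rate Probability a planted topic token is written inside a
#'   negation phrase (default 0.2).
#' @return A `generator_config`; see [generator_config()].
#' @export
default_generator_config <- function(n_patients = 849L, seed = 1L, negation_rate = 0.2) {
  generator_config(
    n_patients = n_patients,
    class_weights = .default_class_sizes / sum(.default_class_sizes),
    item_probs = .default_indicator_pct() / 100,
    age_dist = sweep(.default_age_pct(), 2L, colSums(.default_age_pct()), "/"),
    p_long_gap = c(0.127, 0.185, 0.137, 0.168, 0.108, 0.143),
    vl_detect_prob = c(0.276, 0.398, 0.278, 0.198, 0.318, 0.305),
    sex_male_prob = c(0.667, 1, 0, 0.91, 0.417, 1),
    negation_rate = negation_rate,
    study_start = "2017-01-01",
    study_end = "2020-12-31",
    seed = seed)
}
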