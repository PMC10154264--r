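# Shared fixtures: everything is generated in code, nothing read from disk.

cond_at <- function(tc) seawater_conditions(tc, 35, 8.10)

carb_at <- function(tc) compute_constants(cond_at(tc))

# frozen values from an independent speciation implementation (same
# Mehrbach-NBS formulation, independent arithmetic): CO2 (uM) at
# DIC = 2 mM, S = 35, pH 8.10
oracle_co2_uM <- c("10" = 18.622, "18" = 15.976, "25" = 14.382)

# small jittered parameter sets around the 18 degC preset, deterministic
random_ccm_params <- function(n, seed = 202) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    j <- function(x, s = 0.3) x * exp(stats::rnorm(1, 0, s))
    p <- ccm_preset(18)
    ccm_params(p$conditions, dic_mM = p$dic_mM,
               fc = vapply(p$fc, j, 0),
               fb_frustule = p$fb_frustule,
               fb_plasmalemma_passive = j(p$fb_plasmalemma_passive),
               fb_stroma_pyrenoid = j(p$fb_stroma_pyrenoid),
               ca = c(surface = 0, cytosol = j(p$ca[["cytosol"]]),
                      stroma = 0, pyrenoid = j(p$ca[["pyrenoid"]])),
               vmax_plm = j(p$vmax_plm), k_plm = p$k_plm,
               vmax_env = j(p$vmax_env), k_env = p$k_env,
               kcatC = p$kcatC, KCair_uM = p$KCair_uM,
               abundance = p$abundance, respiration = j(p$respiration))
  })
}

# quick access to the DIC titration levels used in the response-curve assays
dic_titration_mM <- c(0.08, 0.15, 0.25, 0.4, 0.7, 1.0, 1.5, 2.0)
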