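# Shared fixtures: a small synthetic calibration world built in code.
#
# The "scanner" is the stoichiometric forward model with beam-quality
# constants of realistic magnitude (cortical bone ~2080/1280 HU at
# 80/140 kV, air ~ -999 HU).

fix_k_low <- function() stoich_params(6e-5, 1.5e-3, "80kV")
fix_k_high <- function() stoich_params(2e-5, 8e-4, "140kV")

# full reference basis incl. generated spongiosa gap-fillers
fix_basis <- function() default_tissue_basis(with_spongiosa = 4)

fix_tissue <- function(basis, name) {
  basis$tissues[[match(name, vapply(basis$tissues, `[[`, "", "name"))]]
}

# twelve-insert calibration set emulating the insert phantom
fix_insert_names <- function() {
  c("water", "adipose", "muscle", "liver", "brain", "blood", "skin",
    "red_marrow", "yellow_marrow", "cortical_bone", "spongiosa_02", "lung")
}

fix_inserts <- function(basis = fix_basis()) {
  lapply(fix_insert_names(), fix_tissue, basis = basis)
}

# self-consistent calibrated world: noise-free measurements, fitted
# stoichiometric params, basis table and SPR model (memoized per session)
fix_world <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    basis <- fix_basis()
    inserts <- fix_inserts(basis)
    cal <- make_calibration_set(inserts, fix_k_low(), fix_k_high(),
                                sigma = c(0, 0), seed = 7)
    fit_l <- fit_stoich_params(cal$low, beam_label = "80kV")
    fit_h <- fit_stoich_params(cal$high, beam_label = "140kV")
    table <- predict_basis_table(basis, fit_l, fit_h)
    model <- fit_spr_model(inserts,
                           vapply(cal$low, `[[`, 0, "mean_hu"),
                           vapply(cal$high, `[[`, 0, "mean_hu"),
                           basis = basis)
    cache <<- list(basis = basis, inserts = inserts, fit_l = fit_l,
                   fit_h = fit_h, table = table, model = model)
    cache
  }
})

# simple two-element toy tissue for arithmetic checks
fix_co_tissue <- function(wc = 0.5, density = 1.2, name = "toy") {
  tissue(name, c(C = wc, O = 1 - wc), density)
}
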