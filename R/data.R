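# Published reference values shipped with the package.

#' Published elite pole-vault group means and agreement statistics
#'
#' Group means (mean and SD, overall and by sex) and two-method agreement
#' statistics for eight world-class pole vaulters (four men, four women)
#' whose final run-up steps and take-off were analysed at an indoor
#' championship with both manual digitising (the reference method, REF) and a
#' markerless system (ML), as reported in the sports-biomechanics literature.
#' Variable names follow [variable_catalogue()].
#'
#' These tables are worked-example inputs: e.g. the published bias for a
#' variable equals `mean(REF) - mean(ML)` of its published group means, and
#' the published lower limit of agreement equals `bias - random_error`.
#'
#' @return `published_group_means`: data.frame with columns `variable`,
#'   `units`, `group` (ALL/MEN/WOMEN), `ref_mean`, `ref_sd`, `ml_mean`,
#'   `ml_sd`. `published_agreement`: data.frame with columns `variable`,
#'   `units`, `bias`, `random_error`, `loa_low`, `loa_high`, `rmse`,
#'   `icc_3_1`.
#' @export
published_group_means <- function() {
  read.csv(system.file("extdata", "elite_vault_group_means.csv",
                       package = "vaultkin"), stringsAsFactors = FALSE)
}

#' @rdname published_group_means
#' @export
published_agreement <- function() {
  read.csv(system.file("extdata", "elite_vault_agreement_published.csv",
                       package = "vaultkin"), stringsAsFactors = FALSE)
}
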