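#' Docking scores of the ten similarity-search candidates
#'
#' The published rescoring table for the ten compounds retrieved by
#' Tanimoto (> 0.8) similarity search around the first confirmed hit of
#' an IRAK1 screening campaign: six docking scores per compound (Glide SP
#' and XP plus AutoDock, against the two receptor chains 6BFN_A/6BFN_B),
#' the printed consensus average (`AVG`), the classifier's predicted
#' label (`AI_Pred`, 0 = predicted inactive) and the measured IC50 where
#' a compound was assayed (`IC50_uM`, annotation only).
#'
#' @return Data frame with one row per candidate.
#' @examples
#' cand <- similarity_candidates()
#' average_docking(unlist(cand[1, c("SP_A", "SP_B", "XP_A", "XP_B",
#'                                  "AD_A", "AD_B")]))
#' @export
similarity_candidates <- function() {
  path <- system.file("extdata", "similarity_candidates.csv",
                      package = "screenml", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

docking_score_columns <- c("SP_A", "SP_B", "XP_A", "XP_B", "AD_A", "AD_B")
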