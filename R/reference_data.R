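# Published benchmark summaries bundled for predictivity arithmetic.

#' Reference signature-reproduction scores for 17 hepatotoxicity benchmark
#' compounds
#'
#' The classic benchmark panel of calcium modulators, antimitotics, DNA
#' damaging and nuclear receptor agents profiled in HepG2 and HepaRG cells,
#' with the published 0/1 score per compound and cellular model (1 = the
#' mechanism signature was reproduced in that model).
#'
#' @return Data frame with `compound_id`, `mechanism_reference`, `hepg2`
#'   and `heparg` 0/1 scores.
#' @export
#' @examples
#' signature_success(signature_reference_scores()[, c("hepg2", "heparg")])
signature_reference_scores <- function() {
  data.frame(
    compound_id = c("celecoxib", "tamoxifen", "fluphenazine", "methiothepin",
                    "perphenazine", "colchicine", "nocodazole", "noscapine",
                    "teniposide", "camptothecin", "strophanthidin",
                    "etoposide", "benzo_a_pyrene", "budesonide",
                    "hydralazine", "hydrocortisone", "methylprednisolone"),
    mechanism_reference = c(rep("calcium_modulator", 5L),
                            rep("antimitotic", 3L),
                            rep("dna_damaging", 5L),
                            rep("nuclear_receptor", 4L)),
    hepg2  = c(0, 1, 1, 1, 1, 1, 1, 0, 1, 1, 0, 1, 0, 1, 1, 1, 1),
    heparg = c(0, 1, 1, 1, 1, 1, 1, 1, 1, 0, 1, 0, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE)
}

#' Reference confusion counts from a two-project genotoxicity screen
#'
#' Published per-project outcome counts of an 81-compound impedance-based
#' genotoxicity screen (two neuropathic-pain discovery projects, 35 and 46
#' compounds): true/false positives and negatives of the impedance call
#' against the reference genotoxicity battery.
#'
#' @return Data frame with `project`, `tp`, `fp`, `tn`, `fn`.
#' @export
#' @examples
#' counts <- genotox_screen_counts()
#' confusion_summary(sum(counts$tp), sum(counts$fp),
#'                   sum(counts$tn), sum(counts$fn))
genotox_screen_counts <- function() {
  data.frame(project = c("CNS1", "CNS2"),
             tp = c(14L, 0L), fp = c(1L, 1L),
             tn = c(12L, 38L), fn = c(8L, 7L),
             stringsAsFactors = FALSE)
}
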