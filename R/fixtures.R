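#' Load a packaged reference table
#'
#' Small tables transcribed from the study's printed summary tables, used as
#' ground truth in tests and worked examples:
#'
#' * `table1_nodes` - the selected network nodes: 9 shared mRNAs (two of
#'   which, INS and LEP, have no interacting miRNA and are excluded from the
#'   final network), the 7 hub miRNAs (all of degree 4 in the mRNA-miRNA
#'   network) and the 11 hub lncRNAs (3 of degree 7 and 8 of degree 6 in the
#'   miRNA-lncRNA network).
#' * `table4_directions` - the disease regulation direction of each selected
#'   lncRNA in both diabetes and Alzheimer's (shared direction, or `unknown`
#'   for the five lncRNAs without literature support).
#' * `table5_drug_classes` - the 40 training drugs with their interacting
#'   lncRNAs and therapeutic (`positive`, 16 drugs) or exacerbating
#'   (`negative`, 24 drugs) class. The printed source table's interleaved
#'   two-column layout is ambiguous for two entries; this transcription is
#'   reconciled against the stated class totals and the drug identities that
#'   reappear in the screening results.
#' * `effect_verbs` - the controlled vocabulary mapping free-text effect
#'   verbs (inhibits, overexpresses, ...) to `increase`/`decrease`.
#'
#' @param name one of `"table1_nodes"`, `"table4_directions"`,
#'   `"table5_drug_classes"`, `"effect_verbs"`.
#' @return A typed data frame; see Details.
#' @export
#' @examples
#' tab5 <- load_fixture("table5_drug_classes")
#' table(tab5$class)  # 24 negative, 16 positive
load_fixture <- function(name = c("table1_nodes", "table4_directions",
                                  "table5_drug_classes", "effect_verbs")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "crosstalkDR",
                      mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  switch(name,
    table1_nodes = {
      df$layer <- factor(df$layer, levels = c("mrna", "mirna", "lncrna"))
      df$degree <- as.integer(df$degree)
      df$in_final_network <- as.logical(df$in_final_network)
      df
    },
    table4_directions = {
      df$direction_dm <- factor(df$direction_dm, levels = c("up", "down", "unknown"))
      df$direction_ad <- factor(df$direction_ad, levels = c("up", "down", "unknown"))
      df
    },
    table5_drug_classes = {
      df$class <- factor(df$class, levels = c("negative", "positive"))
      df
    },
    effect_verbs = df
  )
}
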