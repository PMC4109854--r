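# A small motif-TF network with the classic association patterns: an
# unannotated motif reachable only through similarity, a motif annotated
# to a non-human TF whose human orthologs form a family, and a directly
# annotated motif.
worked_graph <- function() {
  motif2tf_graph(
    annotations = data.frame(
      motif_id = c("M3", "M4", "M2", "M5"),
      tf_id = c("TF7", "TF1", "TF5", "TF9"),
      species = c("mouse", "human", "fly", "human"),
      stringsAsFactors = FALSE),
    homology = data.frame(
      tf_a = c("TF7", "TF7", "TF7", "TF5", "TF5", "TF5"),
      tf_b = c("TF1", "TF6", "TF8", "TF2", "TF3", "TF4"),
      identity_pct = c(85, 70, 60, 90, 80, 75),
      stringsAsFactors = FALSE),
    similarity = data.frame(
      motif_a = c("M1", "M1"),
      motif_b = c("M3", "M4"),
      p_value = c(5e-4, 1e-4),
      stringsAsFactors = FALSE),
    tf_species = data.frame(
      tf_id = c("TF2", "TF3", "TF4", "TF6", "TF8"),
      species = "human", stringsAsFactors = FALSE))
}
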