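# Shared harness for the planted-signal studies: simulate a dataset,
# scan every species with the full PWM collection and build the motif
# ranking database.
simulate_and_rank <- function(cfg) {
  ds <- simulate_dataset(cfg)
  sc <- do.call(rbind, lapply(names(ds$sequences), function(sp)
    scan_regions(ds$sequences[[sp]], ds$pwms)))
  mids <- unique(sc$motif_id)
  cols <- lapply(seq_along(mids), function(i)
    build_motif_ranking(sc[sc$motif_id == mids[i], , drop = FALSE],
                        ds$annotation$gene_id,
                        seed = cfg$seed * 1000L + i))
  names(cols) <- mids
  db <- ranking_db_from_columns(cols, "motifs",
                                list(seed = cfg$seed))
  list(dataset = ds, db = db)
}

# Detection summary for the planted motif in one enrichment run.
planted_motif_outcome <- function(db, ds, gene_set,
                                  params = recovery_params()) {
  res <- suppressWarnings(run_enrichment(db, gene_set, params))
  idx <- which(res$feature_id == ds$true_motif_id)
  reported <- length(idx) > 0
  sel <- if (reported)
    attr(res, "targets_list")[[paste0("motifs:", ds$true_motif_id)]]$gene_id
  else character()
  pos_in_set <- intersect(gene_set, ds$target_genes)
  list(reported = reported,
       rank1 = reported && idx[1] == 1L,
       nes = if (reported) res$NES[idx[1]] else NA_real_,
       sensitivity = length(intersect(sel, pos_in_set)) /
         max(1L, length(pos_in_set)),
       ppv = length(intersect(sel, ds$target_genes)) /
         max(1L, length(sel)))
}
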