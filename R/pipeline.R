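## End-to-end pipeline: files in, graph construction, stratified holdout,
## cross-validated training, best-fold selection, Youden thresholding,
## hold-out evaluation, gene classification, and report files out.

#' Build a gene graph from input files
#'
#' Reads GWAS summary statistics, gene coordinates, SNP-SNP interactions,
#' omics tables, and labels; selects candidate genes, maps SNPs to genes,
#' aggregates interactions into gene edges, keeps the top edge fraction,
#' splits labels into a stratified train/test holdout, and assembles the
#' graph (preprocessing fitted on the train mask only; the validation
#' mask is stamped later by the cross-validation folds).
#'
#' @param gwas,genes,interactions,labels File paths (see the readers).
#' @param omics Character vector of omics table paths.
#' @param p_threshold,window_bp,snp_window_bp,top_fraction Construction
#'   parameters (defaults: 5e-8, 1 Mb, 1 kb, 0.01).
#' @param holdout_fraction Fraction of labeled genes kept for training
#'   (default 0.8).
#' @param seed Integer seed for the holdout split.
#' @return A `gene_graph` with masks `train` / `test`.
#' @export
build_graph_from_files <- function(gwas, genes, interactions, omics, labels,
                                   p_threshold = 5e-8, window_bp = 1e6,
                                   snp_window_bp = 1000,
                                   top_fraction = 0.01,
                                   holdout_fraction = 0.8, seed = 0L) {
  for (p in c(gwas, genes, interactions, omics, labels))
    if (!file.exists(p)) stop("input file not found: ", p)
  snps <- read_gwas_tsv(gwas)
  gene_tab <- read_gene_bed(genes)
  inter <- read_interactions_tsv(interactions)
  labs <- read_labels_tsv(labels)
  omics_tables <- lapply(omics, read_omics_tsv)

  cand <- select_candidate_genes(snps, gene_tab, p_threshold, window_bp)
  sg_map <- map_snps_to_genes(snps, gene_tab, snp_window_bp)
  edges <- build_gene_edges(inter, sg_map)
  if (nrow(edges)) edges <- filter_top_fraction(edges, top_fraction)

  lab_vec <- c(stats::setNames(rep(1L, length(labs$positives)),
                               labs$positives),
               stats::setNames(rep(0L, length(labs$negatives)),
                               labs$negatives))
  split <- stratified_holdout(lab_vec, holdout_fraction, seed)
  masks <- c(stats::setNames(rep("train", length(split$train)),
                             split$train),
             stats::setNames(rep("test", length(split$test)), split$test))
  assemble_graph(cand, labs, edges, omics_tables, masks)
}

#' Run the full pipeline
#'
#' Graph construction (or a prebuilt graph), stratified holdout, k-fold
#' cross-validated training, best-fold selection, Youden thresholding,
#' hold-out evaluation, and classification of every node, with all
#' artifacts written under `out_dir`: `resolved_config.json`,
#' `history.tsv`, `report.json`, `predictions.tsv`, `edges.tsv`.
#'
#' @param graph A prebuilt `gene_graph` (alternatively pass `files`, a
#'   named list forwarded to [build_graph_from_files()]).
#' @param files Optional named list of input paths.
#' @param out_dir Output directory (created if needed).
#' @param model,loss,train Configs or override lists.
#' @param k Number of cross-validation folds.
#' @param seed Global seed; stage seeds are derived from it.
#' @param no_prototype_loss,no_edges Ablation switches.
#' @return Invisibly, a list with the fitted `cv` object, the predictions
#'   data frame, and the report list.
#' @export
run_pipeline <- function(graph = NULL, files = NULL, out_dir,
                         model = NULL, loss = NULL, train = NULL,
                         k = 5L, seed = 0L,
                         no_prototype_loss = FALSE, no_edges = FALSE) {
  if (is.null(graph)) {
    if (is.null(files)) stop("supply either `graph` or `files`")
    graph <- do.call(build_graph_from_files, c(files, list(seed = seed)))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  loss_cfg <- resolve_config(loss, pgt_loss_config)
  if (no_prototype_loss) loss_cfg$prototype_loss <- FALSE
  train_cfg <- resolve_config(train, pgt_train_config)
  train_cfg$seed <- as.integer(seed) * 100L + train_cfg$seed

  cv <- protogt_cv(graph, k = k, model = model, loss = loss_cfg,
                   train = train_cfg, no_edges = no_edges, seed = seed)
  preds <- predict(cv$model)
  write_predictions_tsv(preds, file.path(out_dir, "predictions.tsv"))
  utils::write.table(cv$model$history, file.path(out_dir, "history.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(graph$edges))
    write_edges_tsv(graph$edges, file.path(out_dir, "edges.tsv"))

  resolved <- list(model = unclass(resolve_config(model, pgt_model_config)),
                   loss = unclass(loss_cfg), train = unclass(train_cfg),
                   k = k, seed = seed,
                   no_prototype_loss = no_prototype_loss,
                   no_edges = no_edges)
  jsonlite::write_json(resolved, file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  report <- write_report(cv, resolved, file.path(out_dir, "report.json"))
  invisible(list(cv = cv, predictions = preds, report = report))
}

#' Assemble and write the evaluation report
#'
#' @param cv A fitted [protogt_cv()] object.
#' @param resolved_config The resolved configuration list.
#' @param path Output JSON path.
#' @return The report list, invisibly written as JSON.
#' @export
write_report <- function(cv, resolved_config, path) {
  ev <- cv$test_eval
  report <- list(
    folds = cv$folds,
    fold_mean = list(val_auprc = mean(cv$folds$val_auprc),
                     val_auprc_sd = stats::sd(cv$folds$val_auprc),
                     val_auroc = mean(cv$folds$val_auroc),
                     val_auroc_sd = stats::sd(cv$folds$val_auroc)),
    best_fold = cv$best_fold,
    threshold = cv$model$threshold,
    test = if (!is.null(ev)) list(auroc = ev$auroc, auprc = ev$auprc,
                                  f1 = ev$f1, n_pos = ev$n_pos,
                                  n_neg = ev$n_neg,
                                  random_baseline_auprc =
                                    random_baseline_auprc(ev$n_pos,
                                                          ev$n_neg)),
    ablations = list(
      no_prototype_loss = isTRUE(resolved_config$no_prototype_loss),
      no_edges = isTRUE(resolved_config$no_edges)))
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(report)
}
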