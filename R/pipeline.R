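# Cohort orchestration: filter -> ploidy -> LOH -> diversity -> tree ->
# CNV -> core/accessory, with per-stage artifacts written before the next
# stage begins and every report number traceable to a stage output.

default_params <- function() {
  list(
    min_depth = 10, min_qual = 25,
    loh_window = 50000L, loh_step = 25000L, loh_max_het = 10L,
    diversity_window = 10000L,
    cnv_window = 1000L, cnv_step = 200L, cnv_edge = 6000L,
    cnv_min_span = 10000L,
    aneuploidy_window = 20000L,
    cluster_k = 1L,
    min_het_sites = 500L
  )
}

#' Cut a tree into k leaf clusters
#'
#' Removes the k-1 longest internal branches and returns the connected leaf
#' groups. Terminal branches are excluded by default because under
#' average-state distances every isolate carries a heterozygosity-driven
#' terminal branch of length ~0.5 x het density that says nothing about
#' population structure; with `include_terminal = TRUE` the longest branches
#' of any kind are cut, which allows an outlier isolate on a long private
#' branch to become a singleton cluster.
#'
#' @param tree An [ape::phylo].
#' @param k Number of clusters (1 to number of leaves).
#' @param include_terminal Also consider terminal branches for cutting.
#' @return Named character vector: cluster label (`"C1"`...`"Ck"`, in leaf
#'   order of first appearance) per leaf.
#' @export
cluster_assign <- function(tree, k, include_terminal = FALSE) {
  n_leaf <- length(tree$tip.label)
  if (k < 1 || k > n_leaf) stop("k must be between 1 and the leaf count")
  cut <- integer(0)
  if (k > 1) {
    candidates <- seq_len(nrow(tree$edge))
    if (!include_terminal) {
      internal <- tree$edge[, 2L] > n_leaf
      if (sum(internal) >= k - 1L) candidates <- candidates[internal]
    }
    cut <- candidates[order(tree$edge.length[candidates],
                            decreasing = TRUE)][seq_len(k - 1L)]
  }
  keep <- setdiff(seq_len(nrow(tree$edge)), cut)
  # union-find over tree nodes with the remaining edges
  n_nodes <- max(tree$edge)
  parent <- seq_len(n_nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in keep) {
    a <- find(tree$edge[e, 1L]); b <- find(tree$edge[e, 2L])
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_len(n_leaf), find, integer(1))
  labels <- paste0("C", as.integer(factor(comp, levels = unique(comp))))
  stats::setNames(labels, tree$tip.label)
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  need <- c("reference", "vcf_dir", "depth_dir", "gff", "outdir")
  missing <- setdiff(need, names(config))
  if (length(missing))
    stop("config is missing: ", paste(missing, collapse = ", "))
  params <- utils::modifyList(default_params(), config$params %||% list())
  config$params <- params
  config
}

stage_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full cohort analysis pipeline
#'
#' Executes filtering, ploidy classification, LOH detection, diversity
#' statistics, tree building with cluster assignment, CNV calling with
#' triploid subgenome attribution, and core/accessory classification, in
#' that order, writing each stage's artifacts under `outdir` before the next
#' stage begins. The pipeline is deterministic: it draws no random numbers.
#'
#' @param config A list, or path to a JSON file, with entries `reference`
#'   (FASTA), `vcf_dir` (one `<isolate>.vcf` per isolate), `depth_dir`
#'   (matching `<isolate>_depth.tsv`), `gff` (gene models), `outdir`, and
#'   optional `params` overriding [default_params()] (notably `cluster_k`).
#' @return A `cohort_report` list: per-isolate table, LOH/CNV/aneuploidy
#'   details, diversity windows (cohort-wide and per cluster), tree path,
#'   cluster labels and core/accessory counts.
#' @export
run_pipeline <- function(config) {
  config <- read_config(config)
  p <- config$params
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  ref <- read_reference_fasta(config$reference)
  genes <- read_genes_gff3(config$gff)
  lens <- scaffold_lengths(ref)

  vcfs <- sort(list.files(config$vcf_dir, pattern = "\\.vcf$",
                          full.names = TRUE))
  if (!length(vcfs)) stop("no VCF files found in ", config$vcf_dir)
  ids <- sub("\\.vcf$", "", basename(vcfs))
  depth_files <- file.path(config$depth_dir, paste0(ids, "_depth.tsv"))
  absent <- !file.exists(depth_files)
  if (any(absent))
    stop("stage input: missing depth file for isolate ",
         paste(ids[absent], collapse = ", "))

  # -- stage 1: read + filter -------------------------------------------
  records <- list()
  iso_rows <- list()
  for (i in seq_along(ids)) {
    raw <- read_vcf(vcfs[i])
    filt <- filter_calls(raw, p$min_depth, p$min_qual)
    records[[ids[i]]] <- filt
    iso_rows[[ids[i]]] <- data.frame(
      isolate = ids[i], n_raw = nrow(raw),
      n_SNPs = nrow(filt),
      n_het = sum(filt$genotype == "het"),
      n_hom = sum(filt$genotype != "het")
    )
    stage_msg("filter", "%s: %d raw, %d kept (%d het, %d hom)", ids[i],
              nrow(raw), nrow(filt), iso_rows[[ids[i]]]$n_het,
              iso_rows[[ids[i]]]$n_hom)
  }
  iso_tab <- do.call(rbind, iso_rows)

  # -- stage 2: ploidy ---------------------------------------------------
  ploidy_calls <- lapply(ids, function(id) {
    het <- records[[id]][records[[id]]$genotype == "het", , drop = FALSE]
    classify_ploidy(balance_histogram(het), min_sites = p$min_het_sites)
  })
  names(ploidy_calls) <- ids
  iso_tab$ploidy_label <- vapply(ploidy_calls, `[[`, "", "label")
  iso_tab$ploidy <- ifelse(iso_tab$ploidy_label == "triploid", 3L, 2L)
  utils::write.table(
    data.frame(isolate = ids,
               n_het_sites = vapply(ploidy_calls, `[[`, 0L, "n_sites"),
               mass_diploid = vapply(ploidy_calls, `[[`, 0, "mass_diploid"),
               mass_triploid = vapply(ploidy_calls, `[[`, 0, "mass_triploid"),
               label = iso_tab$ploidy_label),
    file.path(outdir, "ploidy.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  stage_msg("ploidy", "%s", paste(ids, iso_tab$ploidy_label, collapse = "; "))

  # -- stage 3: LOH ------------------------------------------------------
  loh_list <- list()
  for (id in ids) {
    pos <- het_positions(records[[id]])
    loh <- scan_loh(pos, lens, p$loh_window, p$loh_step, p$loh_max_het)
    loh_list[[id]] <- loh
    rtracklayer::export(loh, file.path(outdir, paste0(id, "_loh.bed")),
                        format = "bed")
    iso_tab[iso_tab$isolate == id, "loh_regions"] <- length(loh)
    iso_tab[iso_tab$isolate == id, "loh_fraction"] <-
      loh_genome_fraction(loh, lens)
    iso_tab[iso_tab$isolate == id, "het_per_kb_excl_loh"] <-
      if (loh_genome_fraction(loh, lens) < 1)
        heterozygosity_excluding_loh(pos, loh, lens) else NA_real_
  }
  stage_msg("loh", "mean genome fraction %.3f", mean(iso_tab$loh_fraction))

  # -- stage 4: alignment + cohort diversity -----------------------------
  aln <- snp_alignment(records, ref)
  masks <- partition_sites(genes, lens)
  div_cohort <- if (length(ids) >= 2L)
    window_scan(aln, p$diversity_window) else NULL
  if (!is.null(div_cohort)) {
    div_cohort$cluster <- "cohort"
    utils::write.table(div_cohort, file.path(outdir, "diversity_cohort.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # -- stage 5: tree + clusters -----------------------------------------
  tree <- NULL; clusters <- stats::setNames(rep("C1", length(ids)), ids)
  if (length(ids) >= 3L) {
    seqs <- polymorphic_matrix(aln)
    dm <- distance_matrix(seqs)
    utils::write.table(dm, file.path(outdir, "distances.tsv"),
                       sep = "\t", quote = FALSE)
    tree <- nj_tree(dm)
    write_newick(tree, file.path(outdir, "tree.nwk"))
    clusters <- cluster_assign(tree, min(p$cluster_k, length(ids)))
    clusters <- clusters[ids]
    stage_msg("tree", "%d polymorphic columns, %d cluster(s)",
              attr(seqs, "n_columns"), length(unique(clusters)))
  }
  iso_tab$cluster <- unname(clusters)

  div_clusters <- list()
  for (cl in unique(clusters)) {
    members <- ids[clusters == cl]
    if (length(members) < 2L) next
    d <- window_scan(aln, p$diversity_window, isolates = members)
    d$cluster <- cl
    div_clusters[[cl]] <- d
  }
  if (length(div_clusters)) {
    utils::write.table(do.call(rbind, div_clusters),
                       file.path(outdir, "diversity_clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # -- stage 6: CNV ------------------------------------------------------
  gene_cn_list <- list(); cnv_out <- list(); aneu_out <- list()
  for (id in ids) {
    track <- read_depth_tsv(file.path(config$depth_dir,
                                      paste0(id, "_depth.tsv")))
    ploidy <- iso_tab$ploidy[iso_tab$isolate == id]
    ratios <- normalize_ratios(track, p$cnv_window, p$cnv_step, p$cnv_edge)
    segs <- segment_cn(ratios, ploidy, p$cnv_min_span)
    aneu <- detect_aneuploidy(coverage_windows(track, p$aneuploidy_window),
                              ploidy)
    aneu$isolate <- id
    aneu_out[[id]] <- aneu
    gene_cn_list[[id]] <- gene_copy_number(segs, genes, ploidy)

    config_lab <- rep(NA_character_, length(segs))
    if (ploidy == 3L && length(segs)) {
      recs <- records[[id]]
      for (k in which(segs$klass != "neutral")) {
        scf <- as.character(GenomicRanges::seqnames(segs)[k])
        inside <- recs$scaffold == scf &
          recs$pos >= GenomicRanges::start(segs)[k] &
          recs$pos <= GenomicRanges::end(segs)[k]
        ab <- allele_balance(recs[inside, , drop = FALSE])
        config_lab[k] <- subgenome_attribution(segs$klass[k], ab)$configuration
      }
    }
    segs$configuration <- config_lab
    cnv_out[[id]] <- segs
    bed <- segs
    bed$name <- paste(bed$copy_number, bed$klass,
                      ifelse(is.na(bed$configuration), ".",
                             bed$configuration), sep = ":")
    S4Vectors::mcols(bed) <- S4Vectors::DataFrame(name = bed$name)
    rtracklayer::export(bed, file.path(outdir, paste0(id, "_cnv.bed")),
                        format = "bed")
    iso_tab[iso_tab$isolate == id, "n_gains"] <- sum(segs$klass == "gain")
    iso_tab[iso_tab$isolate == id, "n_losses"] <- sum(segs$klass == "loss")
    iso_tab[iso_tab$isolate == id, "n_aneuploid_scaffolds"] <-
      sum(aneu$call != "euploid")
  }
  stage_msg("cnv", "done for %d isolates", length(ids))

  # -- stage 7: pangenome ------------------------------------------------
  cn_matrix <- gene_cn_matrix(gene_cn_list)
  utils::write.table(cn_matrix, file.path(outdir, "gene_cn_matrix.tsv"),
                     sep = "\t", quote = FALSE)
  pan <- core_accessory(cn_matrix)
  stage_msg("pangenome", "%d core / %d accessory genes", pan$core,
            pan$accessory)

  utils::write.table(iso_tab, file.path(outdir, "isolates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- list(
    isolates = iso_tab,
    ploidy_calls = ploidy_calls,
    loh = loh_list,
    diversity_cohort = div_cohort,
    diversity_clusters = div_clusters,
    tree = tree,
    clusters = clusters,
    cnv = cnv_out,
    aneuploidy = do.call(rbind, aneu_out),
    gene_cn = cn_matrix,
    pangenome = pan,
    params = p
  )
  class(report) <- "cohort_report"
  json <- list(
    isolates = iso_tab,
    clusters = as.list(clusters),
    pangenome = list(core = pan$core, accessory = pan$accessory)
  )
  jsonlite::write_json(json, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("cohort_report:", nrow(x$isolates), "isolates,",
      length(unique(x$clusters)), "cluster(s),",
      x$pangenome$core, "core /", x$pangenome$accessory,
      "accessory genes\n")
  invisible(x)
}
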