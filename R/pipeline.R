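#' Read a plain-text run configuration
#'
#' A minimal `key: value` format, one entry per line; `#` starts a
#' comment. A key repeated on several lines collects its values into a
#' vector (that is how multiple groups or comparison pairs are listed);
#' values convert to numeric where possible. Group selectors use the
#' form `condition=red,genotype=WT`.
#'
#' @param path Config file path.
#' @return Named list of values.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[lines != ""]
  cfg <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:]+):(.*)$", ln))[[1L]]
    if (length(m) != 3L) stop2("bad config line: ", ln)
    key <- trimws(m[2L]); val <- trimws(m[3L])
    suppressWarnings(num <- as.numeric(val))
    if (!is.na(num)) val <- num
    cfg[[key]] <- c(cfg[[key]], val)
  }
  cfg
}

parse_group <- function(spec) {
  kv <- strsplit(strsplit(spec, ",")[[1L]], "=")
  out <- stats::setNames(vapply(kv, function(x) trimws(x[2L]), character(1)),
                         vapply(kv, function(x) trimws(x[1L]), character(1)))
  if (!all(c("condition", "genotype") %in% names(out)))
    stop2("group spec needs condition=... and genotype=...: ", spec)
  out
}

#' Run the full analysis pipeline
#'
#' Ingest -> annotation filter -> expressed filter -> rhythm detection per
#' group -> pairwise circadiome comparison -> promoter motif scan ->
#' phase-enrichment z-scores, with every stage's outputs written as TSV
#' under `out_dir` and a plain-text manifest recording the configuration,
#' the seed, and the counts at every stage. All stage outputs are pure
#' functions of (inputs, config, seed); rerunning the same config
#' reproduces them byte for byte.
#'
#' @param config A list with elements: `matrix`, `design`, `annotation`
#'   (paths) or `dataset` (an [expression_dataset] directly); `groups`
#'   (character vector of `condition=..,genotype=..` selectors); `params`
#'   (a [rhythm_params]); optional `compare` (list of 2-long vectors of
#'   group indices); optional `promoters` (FASTA path) and `motifs`
#'   (named IUPAC patterns; default [circadian_motifs()]); optional
#'   `enrich` (list with `window`, `B`, `seed`); `out_dir`.
#' @return The manifest, invisibly (a named list), also written to
#'   `manifest.txt`.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir %||% stop2("config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(started = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   package_version = as.character(
                     utils::packageVersion("circadiome")))

  ds <- if (!is.null(config$dataset)) config$dataset else
    read_expression_table(config$matrix, config$design, config$annotation)
  manifest$probes_in <- nrow(ds$values)

  ds <- filter_annotation(ds)
  manifest$probes_after_annotation <- nrow(ds$values)

  groups <- lapply(config$groups, parse_group)
  if (length(groups) == 0L) stop2("config$groups is required")
  grp_df <- data.frame(
    condition = vapply(groups, `[[`, character(1), "condition"),
    genotype = vapply(groups, `[[`, character(1), "genotype"))
  for (i in seq_len(nrow(grp_df)))
    group_columns(ds, grp_df$condition[i], grp_df$genotype[i])  # validate

  params <- config$params
  if (!inherits(params, "rhythm_params")) stop2("config$params must be rhythm_params")
  expressed <- filter_expressed(ds, grp_df, params$floor_fraction)
  manifest$probes_expressed <- length(expressed)

  calls <- list()
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    tag <- paste0(g[["condition"]], "_", g[["genotype"]])
    calls[[tag]] <- classify_all(ds, g[["condition"]], g[["genotype"]],
                                 params, probes = expressed)
    write_rhythm_calls(calls[[tag]],
                       file.path(out_dir, paste0("calls_", tag, ".tsv")))
    manifest[[paste0("n_rhythmic_", tag)]] <- sum(calls[[tag]]$rhythmic)
  }

  if (!is.null(config$compare)) {
    for (pair in config$compare) {
      ta <- names(calls)[pair[1L]]; tb <- names(calls)[pair[2L]]
      cmp <- compare_rhythm_sets(calls[[ta]], calls[[tb]],
                                 params$period_h, params$phase_step_h)
      prefix <- file.path(out_dir, paste0("compare_", ta, "_vs_", tb))
      utils::write.table(cmp$phase_crosstab, paste0(prefix, "_crosstab.tsv"),
                         sep = "\t", quote = FALSE)
      writeLines(c(cmp$set_both), paste0(prefix, "_both.txt"))
      writeLines(c(cmp$set_a_only), paste0(prefix, "_a_only.txt"))
      writeLines(c(cmp$set_b_only), paste0(prefix, "_b_only.txt"))
      manifest[[paste0("shared_", ta, "_vs_", tb)]] <- length(cmp$set_both)
      manifest[[paste0("median_shift_", ta, "_vs_", tb)]] <-
        cmp$phase_shift_median_h
    }
  }

  if (!is.null(config$promoters)) {
    promoters <- read_promoters(config$promoters)
    motifs <- config$motifs %||% circadian_motifs()
    mt <- gene_motif_table(promoters, motifs)
    utils::write.table(mt$counts,
                       file.path(out_dir, "motif_counts.tsv"),
                       sep = "\t", quote = FALSE)
    manifest$n_promoters <- length(promoters)

    if (!is.null(config$enrich)) {
      en <- config$enrich
      if (is.null(en$seed)) stop2("enrich stage requires a seed")
      map_gene <- function(ids) {
        agi <- ds$annotation$agi_code[match(ids, ds$annotation$probe_id)]
        ifelse(is.na(agi), ids, agi)
      }
      for (tag in names(calls)) {
        cc <- calls[[tag]]
        genes <- map_gene(cc$probe_id)
        for (mname in colnames(mt$presence)) {
          flags <- stats::setNames(rep(FALSE, nrow(cc)), cc$probe_id)
          known <- genes %in% rownames(mt$presence)
          flags[known] <- mt$presence[genes[known], mname]
          if (!any(flags[cc$rhythmic])) next
          prof <- zscore_profile(cc, flags,
                                 window = en$window %||% 4L,
                                 B = en$B %||% 100L, seed = en$seed,
                                 period_h = params$period_h,
                                 phase_step_h = params$phase_step_h)
          utils::write.table(
            prof, file.path(out_dir,
                            paste0("enrich_", tag, "_", mname, ".tsv")),
            sep = "\t", quote = FALSE, row.names = FALSE)
        }
      }
      manifest$enrich_seed <- en$seed
    }
  }

  manifest$params <- sprintf(
    "period=%g, step=%g, alpha=%g, fold=%g, abs_mult=%g, floor=%g",
    params$period_h, params$phase_step_h, params$alpha,
    params$fold_threshold, params$abs_change_multiplier,
    params$floor_fraction)
  lines <- paste0(names(manifest), ": ",
                  vapply(manifest, function(x) paste(format(x), collapse = ","),
                         character(1)))
  writeLines(lines, file.path(out_dir, "manifest.txt"))
  invisible(manifest)
}
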