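#' Expression dataset container
#'
#' Bundles a genes x samples expression matrix with its sample design
#' (condition, genotype, hours in constant light) and gene annotation
#' (AGI code, subcellular compartment of the encoding genome). The grand
#' mean -- the mean of all retained probe values across all arrays -- is
#' carried on the object because downstream rhythmicity criteria (the
#' 5% expressed floor and the absolute-change amplitude test) are defined
#' relative to it. It is recomputed whenever probes are filtered, so the
#' value used at classification time always reflects the retained set.
#'
#' @param values Numeric matrix, rows = probes, columns = samples. Row and
#'   column names are required and must be unique. No missing values.
#' @param design `data.frame` with columns `sample_id`, `condition`,
#'   `genotype`, `time_h`; one row per column of `values`, same order.
#' @param annotation `data.frame` with columns `probe_id`, `agi_code`
#'   (`NA` or `""` when absent) and `compartment` (one of `"nuclear"`,
#'   `"mitochondrial"`, `"chloroplastic"`); one row per row of `values`.
#' @return An object of class `expression_dataset`: a list with elements
#'   `values`, `design`, `annotation`, `grand_mean`.
#' @examples
#' ds <- simulate_expression(synthetic_dataset_spec(n_genes = 20, seed = 1))$dataset
#' ds
#' @export
expression_dataset <- function(values, design, annotation) {
  if (!is.matrix(values) || !is.numeric(values))
    stop2("'values' must be a numeric matrix")
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop2("missing value at probe '", rownames(values)[bad[1L]],
          "', sample '", colnames(values)[bad[2L]], "'")
  }
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop2("'values' must have probe row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop2("duplicate probe_id: ",
          rownames(values)[anyDuplicated(rownames(values))])
  design <- as.data.frame(design)
  need <- c("sample_id", "condition", "genotype", "time_h")
  if (!all(need %in% names(design)))
    stop2("design must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stop2("duplicate sample_id in design")
  missing_s <- setdiff(colnames(values), design$sample_id)
  if (length(missing_s))
    stop2("sample missing from design: ", paste(missing_s, collapse = ", "))
  design <- design[match(colnames(values), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  for (g in split(design, paste(design$condition, design$genotype))) {
    if (anyDuplicated(g$time_h))
      stop2("duplicate time_h within group (", g$condition[1L], ", ",
            g$genotype[1L], ")")
  }
  annotation <- as.data.frame(annotation)
  need <- c("probe_id", "agi_code", "compartment")
  if (!all(need %in% names(annotation)))
    stop2("annotation must have columns ", paste(need, collapse = ", "))
  missing_p <- setdiff(rownames(values), annotation$probe_id)
  if (length(missing_p))
    stop2("probe missing from annotation: ",
          paste(utils::head(missing_p, 5L), collapse = ", "))
  annotation <- annotation[match(rownames(values), annotation$probe_id), ,
                           drop = FALSE]
  rownames(annotation) <- NULL
  ok <- annotation$compartment %in%
    c("nuclear", "mitochondrial", "chloroplastic")
  if (!all(ok))
    stop2("unknown compartment: ",
          paste(unique(annotation$compartment[!ok]), collapse = ", "))
  structure(
    list(values = values, design = design, annotation = annotation,
         grand_mean = mean(values)),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset: ", nrow(x$values), " probes x ",
      ncol(x$values), " samples\n", sep = "")
  grp <- unique(x$design[, c("condition", "genotype")])
  cat("groups: ",
      paste(paste0(grp$condition, "/", grp$genotype), collapse = ", "),
      "\n", sep = "")
  cat("grand mean: ", format(x$grand_mean, digits = 6), "\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Read an expression matrix with design and annotation tables
#'
#' Expects delimited text (TSV by default, comma also detected): the matrix
#' with `probe_id` as its first column and sample ids as the remaining
#' headers; a design table with columns `sample_id`, `condition`,
#' `genotype`, `time_h`; and an annotation table with columns `probe_id`,
#' `agi_code` (blank allowed) and `compartment`. Every cell of the matrix
#' must be numeric -- missing values are an ingestion error, not imputed.
#'
#' @param path Path to the expression matrix.
#' @param design_path Path to the sample design table.
#' @param annotation_path Path to the gene annotation table.
#' @return An [expression_dataset]; column order follows the matrix file.
#' @export
read_expression_table <- function(path, design_path, annotation_path) {
  mat_df <- read_delim_auto(path)
  if (ncol(mat_df) < 2L) stop2("expression table needs >= 1 sample column")
  probes <- as.character(mat_df[[1L]])
  vals <- mat_df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad))
        stop2("non-numeric cell at probe '", probes[bad[1L]],
              "', sample '", names(vals)[j], "': '", col[bad[1L]], "'")
      col <- num
    }
    if (anyNA(col))
      stop2("missing cell at probe '", probes[which(is.na(col))[1L]],
            "', sample '", names(vals)[j], "'")
    vals[[j]] <- col
  }
  values <- as.matrix(vals)
  rownames(values) <- probes
  design <- read_delim_auto(design_path)
  annotation <- read_delim_auto(annotation_path)
  expression_dataset(values, design, annotation)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

#' Drop unannotated and organellar probes
#'
#' Retains only probes that carry an AGI code and are annotated as
#' nuclear; probes for mitochondrial and chloroplastic genes, and probes
#' with no gene assignment, are excluded before any rhythm analysis.
#' The grand mean is recomputed on the retained set.
#'
#' @param ds An [expression_dataset].
#' @return Filtered [expression_dataset].
#' @export
filter_annotation <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  agi <- ds$annotation$agi_code
  keep <- !is.na(agi) & agi != "" & ds$annotation$compartment == "nuclear"
  if (!any(keep)) stop2("no analyzable probes after annotation filter")
  subset_probes(ds, which(keep))
}

subset_probes <- function(ds, idx) {
  expression_dataset(ds$values[idx, , drop = FALSE], ds$design,
                     ds$annotation[idx, , drop = FALSE])
}

group_columns <- function(ds, condition, genotype) {
  sel <- ds$design$condition == condition & ds$design$genotype == genotype
  if (!any(sel))
    stop2("group not present in design: condition=", condition,
          ", genotype=", genotype)
  which(sel)
}

#' Non-expressed probe filter
#'
#' A probe is discarded only when its mean expression is below
#' `floor_fraction` of the joint grand mean in *every* group considered;
#' expression above the floor in at least one (condition, genotype) group
#' retains it. The groups considered default to all groups in the design.
#'
#' @param ds An [expression_dataset] (typically after [filter_annotation]).
#' @param groups Optional data.frame/list of `condition`, `genotype` pairs;
#'   default every group in the design.
#' @param floor_fraction Fraction of the grand mean defining the floor
#'   (default 0.05, i.e. 5%). Must lie in `[0, 1)`; 0 retains everything.
#' @return Character vector of retained probe ids.
#' @export
filter_expressed <- function(ds, groups = NULL, floor_fraction = 0.05) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (!is.numeric(floor_fraction) || length(floor_fraction) != 1L ||
      floor_fraction < 0 || floor_fraction >= 1)
    stop2("'floor_fraction' must lie in [0, 1)")
  if (is.null(groups))
    groups <- unique(ds$design[, c("condition", "genotype")])
  groups <- as.data.frame(groups)
  floor_val <- floor_fraction * ds$grand_mean
  keep <- rep(FALSE, nrow(ds$values))
  for (i in seq_len(nrow(groups))) {
    cols <- group_columns(ds, groups$condition[i], groups$genotype[i])
    keep <- keep | rowMeans(ds$values[, cols, drop = FALSE]) >= floor_val
  }
  rownames(ds$values)[keep]
}

#' Median dynamic range over a probe set
#'
#' The median across probes of max/min expression over that probe's
#' samples; a flat transcriptome gives 1.
#'
#' @param ds An [expression_dataset].
#' @param probes Probe ids to include; default all.
#' @return A single number `>= 1`.
#' @export
median_dynamic_range <- function(ds, probes = rownames(ds$values)) {
  stopifnot(inherits(ds, "expression_dataset"))
  m <- ds$values[probes, , drop = FALSE]
  mins <- apply(m, 1L, min)
  if (any(mins <= 0))
    stop2("non-positive minimum for probe: ",
          rownames(m)[which(mins <= 0)[1L]])
  stats::median(apply(m, 1L, max) / mins)
}

#' Equalise per-array medians
#'
#' Scales each array (column) so that its median equals the across-array
#' median of medians. This is a convenience rescaling only: it is NOT
#' equivalent to model-based invariant-set microarray normalization, and a
#' message says so on every use.
#'
#' @param ds An [expression_dataset].
#' @return Rescaled [expression_dataset].
#' @export
rescale_arrays <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  med <- apply(ds$values, 2L, stats::median)
  target <- stats::median(med)
  msg_log("rescale_arrays: simple median scaling; ",
          "not equivalent to model-based array normalization")
  values <- sweep(ds$values, 2L, target / med, `*`)
  expression_dataset(values, ds$design, ds$annotation)
}
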