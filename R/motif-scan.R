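#' Recognised circadian cis elements
#'
#' The IUPAC consensus patterns of promoter elements with documented
#' circadian clock association: the evening element bound by CCA1/LHY,
#' the two TCP binding sites (the CHE-bound GGTCC core and the CCA1-bound
#' GGCCCA site), the G-box bound by HY5/PIFs, the FHY3/FAR1 binding site
#' (fbs), the two GA/CT-rich CCA1-associated motifs, and the morning
#' element of morning-phased promoters (CCACAC, the field's standard
#' consensus). Elements and their reverse complements (e.g. GGCCCA and
#' TGGGCC) are treated as one site: scanning always covers both strands.
#'
#' @return Named character vector of IUPAC patterns.
#' @examples
#' circadian_motifs()
#' @export
circadian_motifs <- function() {
  c(evening_element = "AAAATATC",
    TBS_GGTCC       = "GGTCC",
    TBS_GGCCCA      = "GGCCCA",
    G_box           = "CACGTG",
    fbs             = "CACGCGC",
    GA_motif_1      = "GAGAGAGAGA",
    GA_motif_2      = "RRAGAAGAAG",
    morning_element = "CCACAC")
}

IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

check_iupac <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1L]]
  if (length(chars) == 0L) stop2("empty motif pattern")
  bad <- setdiff(chars, IUPAC_CHARS)
  if (length(bad))
    stop2("non-IUPAC character in pattern: ", paste(bad, collapse = ", "))
  paste(chars, collapse = "")
}

#' Reverse complement of an IUPAC sequence
#'
#' Standard reverse complement extended to the full degenerate alphabet
#' (R <-> Y, S <-> S, W <-> W, K <-> M, B <-> V, D <-> H, N <-> N).
#'
#' @param seq A single IUPAC DNA string.
#' @return The reverse complement.
#' @examples
#' reverse_complement("GGCCCA")  # "TGGGCC"
#' @export
reverse_complement <- function(seq) {
  seq <- check_iupac(seq)
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
            S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
            D = "H", H = "D", N = "N")
  paste(rev(comp[strsplit(seq, "")[[1L]]]), collapse = "")
}

#' Read promoter sequences from FASTA
#'
#' One record per gene, record id = gene (AGI) code, sequence supplied
#' 5'->3' on the gene's strand with its last base immediately upstream of
#' the transcription start site. Sequences are uppercased; records longer
#' than `length_bp` are truncated to the TSS-proximal end, shorter records
#' are kept with a warning.
#'
#' @param fasta Path to a FASTA file.
#' @param length_bp Promoter length convention (default 500 bp upstream
#'   of the TSS).
#' @return Named character vector of promoter sequences.
#' @export
read_promoters <- function(fasta, length_bp = 500L) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) == 0L) stop2("empty promoter FASTA: ", fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop2("duplicate promoter id: ", ids[anyDuplicated(ids)])
  out <- toupper(as.character(seqs))
  names(out) <- ids
  long <- nchar(out) > length_bp
  ## keep the 3' (TSS-proximal) end
  out[long] <- substring(out[long], nchar(out[long]) - length_bp + 1L)
  if (any(nchar(out) < length_bp))
    warning(sum(nchar(out) < length_bp), " promoter(s) shorter than ",
            length_bp, " bp retained as-is", call. = FALSE)
  out
}

#' Scan one sequence for an IUPAC motif on both strands
#'
#' Exact IUPAC matching (degenerate codes in the pattern expand; `N` or
#' other degenerate bases in the promoter never match), overlapping
#' matches allowed. Offsets are reported in bp upstream of the TSS:
#' position 1 is the base immediately upstream of the TSS, and a match's
#' offset is the distance of its 3'-most (TSS-nearest) base.
#'
#' @param seq One promoter sequence (character), 3' end adjacent to TSS.
#' @param pattern IUPAC motif pattern.
#' @param motif Name to record for the motif (defaults to the pattern).
#' @return `data.frame` with columns `motif`, `strand` (`+`/`-`) and
#'   `offset_bp_upstream`, ordered by ascending offset, `+` before `-`.
#' @export
scan_sequence <- function(seq, pattern, motif = pattern) {
  pattern <- check_iupac(pattern)
  seq <- toupper(seq)
  L <- nchar(seq)
  k <- nchar(pattern)
  empty <- data.frame(motif = character(), strand = character(),
                      offset_bp_upstream = integer())
  if (L < k) return(empty)
  subj <- Biostrings::DNAString(seq)
  hits_one <- function(pat, strand) {
    m <- Biostrings::matchPattern(pat, subj, fixed = "subject")
    if (length(m) == 0L) return(empty)
    ## sequence index s (1-based from 5' end) -> bp upstream of TSS for the
    ## match's 3'-most base: offset = L - (s + k - 1) + 1
    starts <- Biostrings::start(m)
    data.frame(motif = motif, strand = strand,
               offset_bp_upstream = L - starts - k + 2L)
  }
  out <- rbind(hits_one(pattern, "+"),
               hits_one(reverse_complement(pattern), "-"))
  out[order(out$offset_bp_upstream, out$strand != "+"), , drop = FALSE]
}

#' Gene x motif occurrence table
#'
#' Counts both-strand IUPAC matches of each motif in each promoter.
#'
#' @param promoters Named character vector from [read_promoters].
#' @param motifs Named character vector of IUPAC patterns
#'   (default [circadian_motifs()]).
#' @return List with `counts` (integer gene x motif matrix), `presence`
#'   (logical matrix, count >= 1) and `hits` (combined hit data.frame
#'   with a `gene` column).
#' @export
gene_motif_table <- function(promoters, motifs = circadian_motifs()) {
  if (is.null(names(motifs)) || any(names(motifs) == ""))
    names(motifs) <- motifs
  set <- Biostrings::DNAStringSet(toupper(promoters))
  L <- nchar(promoters)
  counts <- matrix(0L, nrow = length(promoters), ncol = length(motifs),
                   dimnames = list(names(promoters), names(motifs)))
  hit_list <- list()
  for (m in seq_along(motifs)) {
    pat <- check_iupac(motifs[[m]])
    k <- nchar(pat)
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pat else reverse_complement(pat)
      mm <- Biostrings::vmatchPattern(p, set, fixed = "subject")
      n_hit <- lengths(mm)
      counts[, m] <- counts[, m] + n_hit
      if (any(n_hit > 0)) {
        starts <- unlist(Biostrings::startIndex(mm)[n_hit > 0],
                         use.names = FALSE)
        hit_list[[length(hit_list) + 1L]] <- data.frame(
          gene = rep(names(promoters)[n_hit > 0], n_hit[n_hit > 0]),
          motif = names(motifs)[m], strand = strand,
          offset_bp_upstream =
            rep(L[n_hit > 0], n_hit[n_hit > 0]) - starts - k + 2L)
      }
    }
  }
  hits <- if (length(hit_list)) do.call(rbind, hit_list) else
    data.frame(gene = character(), motif = character(),
               strand = character(), offset_bp_upstream = integer())
  hits <- hits[order(match(hits$gene, names(promoters)),
                     match(hits$motif, names(motifs)),
                     hits$offset_bp_upstream, hits$strand != "+"), ,
               drop = FALSE]
  rownames(hits) <- NULL
  list(counts = counts, presence = counts >= 1L, hits = hits)
}

#' Positional distribution of motif hits
#'
#' Histogram of hit offsets (bp upstream of the TSS) over given bin
#' edges, with the fraction of hits falling in the 50-100 bp
#' TSS-proximal window reported as a convenience.
#'
#' @param hits Hit data.frame (from [scan_sequence] or
#'   [gene_motif_table]`$hits`).
#' @param bin_edges_bp Breaks for the histogram (default 50-bp bins over
#'   a 500-bp promoter).
#' @return List `counts` (named by bin), `fraction_50_100`.
#' @export
positional_distribution <- function(hits, bin_edges_bp = seq(0, 500, 50)) {
  off <- hits$offset_bp_upstream
  bins <- cut(off, breaks = bin_edges_bp, include.lowest = FALSE,
              right = TRUE)
  counts <- c(unclass(table(bins)))
  frac <- if (length(off)) mean(off >= 50 & off <= 100) else NA_real_
  list(counts = counts, fraction_50_100 = frac)
}

#' Motif enrichment of a gene set
#'
#' Fold enrichment of motif presence in a gene set relative to a
#' background set, with a hypergeometric upper-tail p-value (probability
#' of at least the observed number of carriers in a draw of the set's
#' size from the background).
#'
#' @param gene_set Character vector, subset of `background_set`.
#' @param background_set Character vector of background genes.
#' @param presence Logical vector or one-column of the presence matrix
#'   from [gene_motif_table], named by gene.
#' @return List `fold`, `p_value`, `k` (carriers in set), `n` (set size),
#'   `K` (carriers in background), `N` (background size).
#' @export
set_enrichment <- function(gene_set, background_set, presence) {
  if (length(gene_set) == 0L) stop2("empty gene set")
  if (!all(gene_set %in% background_set))
    stop2("gene_set must be a subset of background_set")
  carriers <- names(presence)[presence]
  N <- length(background_set)
  K <- sum(background_set %in% carriers)
  n <- length(gene_set)
  k <- sum(gene_set %in% carriers)
  fold <- if (K == 0L) NA_real_ else (k / n) / (K / N)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  list(fold = fold, p_value = p, k = k, n = n, K = K, N = N)
}
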