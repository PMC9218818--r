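options(circadiome.verbose = FALSE)

## small in-code dataset: ng genes x samples over two groups
make_tiny_dataset <- function(values, times = c(24, 32, 40, 48),
                              condition = "red", genotype = "WT",
                              compartment = "nuclear") {
  ng <- nrow(values)
  rownames(values) <- sprintf("P%03d", seq_len(ng))
  colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  design <- data.frame(sample_id = colnames(values),
                       condition = condition, genotype = genotype,
                       time_h = times)
  annotation <- data.frame(probe_id = rownames(values),
                           agi_code = sprintf("AT1G%05d", seq_len(ng)),
                           compartment = rep_len(compartment, ng))
  expression_dataset(values, design, annotation)
}

## independent IUPAC scan oracle: regex with lookahead for overlaps,
## both strands, offsets in bp upstream of TSS of the 3'-most base
iupac_regex <- function(pattern) {
  cls <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
           S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
           D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste(cls[strsplit(toupper(pattern), "")[[1]]], collapse = "")
}

oracle_scan <- function(seq, pattern) {
  seq <- toupper(seq)
  L <- nchar(seq); k <- nchar(pattern)
  one <- function(pat, strand) {
    m <- gregexpr(paste0("(?=", iupac_regex(pat), ")"), seq,
                  perl = TRUE)[[1]]
    s <- as.integer(m)
    s <- s[s > 0]
    if (!length(s)) return(NULL)
    data.frame(strand = strand, offset = L - s - k + 2L)
  }
  rc <- circadiome::reverse_complement(pattern)
  rbind(one(pattern, "+"), one(rc, "-"))
}

oracle_count <- function(seq, pattern) {
  h <- oracle_scan(seq, pattern)
  if (is.null(h)) 0L else nrow(h)
}

random_dna <- function(n, length_bp = 500) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), length_bp, replace = TRUE),
          collapse = ""), character(1))
}

## dense brute-force phase oracle: argmax of Pearson r over a 0.01-h grid
dense_phase_oracle <- function(series_mat, times_h, step = 0.01,
                               period = 24) {
  phases <- seq(0, period - step, by = step)
  tmpl <- outer(times_h, phases, function(t, p)
    cos(2 * pi * (t - p) / period))
  r <- suppressWarnings(stats::cor(series_mat, tmpl))
  phases[max.col(r, ties.method = "first")]
}
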