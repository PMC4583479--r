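# Small panels and hand-built fixtures shared across test files.

small_panel <- function(seed = 1, density = 400, region = 1e6, ...) {
  synthesize_panel(panel_params(target_density = density, seed = seed, ...),
                   region_length = region)
}

# A panel built directly from a haplotype matrix (no generative model).
manual_panel <- function(haps, positions = seq_len(ncol(haps)) * 100L,
                         population = "TOY", region_length = NULL,
                         is_coding = FALSE) {
  M <- ncol(haps)
  v <- data.frame(id = sprintf("m%03d", seq_len(M)), position = positions,
                  ref = "A", alt = "G",
                  ancestral_freq = pmin(pmax(colMeans(haps), 1e-6), 1 - 1e-6),
                  freq = colMeans(haps),
                  is_coding = rep_len(is_coding, M), stringsAsFactors = FALSE)
  finemapsim:::new_haplotype_panel(
    population, v, haps,
    region_length %||% (max(positions) + 100), model = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# nearest achievable risk-allele frequency in a panel (either orientation)
achievable_raf <- function(panel, target) {
  f <- panel_freq(panel)
  cand <- c(f, 1 - f)
  cand[which.min(abs(cand - target))]
}

# binary column with allele frequency 0.5 and a controlled correlation to x:
# flipping m/2 carriers and m/2 non-carriers gives r = 1 - m/100 at H = 200
flip_some <- function(x, m) {
  y <- x
  ones <- which(x == 1L)[seq_len(m / 2)]
  zeros <- which(x == 0L)[seq_len(m / 2)]
  y[ones] <- 0L
  y[zeros] <- 1L
  y
}

# hard-call study built directly from genotype counts per arm
study_from_counts <- function(case_counts, ctrl_counts) {
  g_case <- rep(0:2, case_counts)
  g_ctrl <- rep(0:2, ctrl_counts)
  dos <- matrix(c(g_case, g_ctrl), ncol = 1)
  y <- c(rep(1L, length(g_case)), rep(0L, length(g_ctrl)))
  haps <- matrix(0L, 2, 1)
  haps[1, 1] <- 1L
  pnl <- manual_panel(haps, positions = 10L)
  finemapsim:::new_study_genotypes(dos, y, pnl, "toy")
}
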