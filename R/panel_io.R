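#' Write a haplotype panel as a phased VCF
#'
#' Emits a VCF v4.2 file with one sample column per individual (two phased
#' haplotypes, `GT` like `0|1`). Positions are written 1-based (internally
#' the package uses 0-based coordinates). The model allele frequency and the
#' coding annotation travel in the `INFO` column (`AF`, `CODING`).
#'
#' @param panel A `haplotype_panel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "haplotype_panel"))
  v <- panel$variants
  H <- nrow(panel$haplotypes)
  n_ind <- H / 2
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=1,length=%d>", as.integer(panel$region_length)),
    sprintf("##population=%s", panel$population),
    sprintf("##region_length=%d", as.integer(panel$region_length)),
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Model alternate allele frequency\">",
    "##INFO=<ID=CODING,Number=0,Type=Flag,Description=\"Variant inside a synthetic exon\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sprintf("SAMPLE%04d", seq_len(n_ind))), collapse = "\t"))
  info <- sprintf("AF=%.10g", v$ancestral_freq)
  info[v$is_coding] <- paste0(info[v$is_coding], ";CODING")
  gt <- matrix("", nrow(v), n_ind)
  h1 <- t(panel$haplotypes[seq(1, H, 2), , drop = FALSE])
  h2 <- t(panel$haplotypes[seq(2, H, 2), , drop = FALSE])
  for (j in seq_len(n_ind)) gt[, j] <- paste0(h1[, j], "|", h2[, j])
  lines <- do.call(paste, c(list("1", v$position + 1L, v$id, v$ref, v$alt,
                                 ".", "PASS", info, "GT"),
                            lapply(seq_len(n_ind), function(j) gt[, j]),
                            sep = "\t"))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a phased biallelic VCF into a haplotype panel
#'
#' Accepts phased, biallelic SNV records only; an unphased genotype
#' (`0/1`) or a multiallelic ALT is rejected with the offending position in
#' the error message. Panels read from VCF carry no generative block model,
#' so they can be used for LD lookups and fine-mapping but not for
#' [derive_diverged_panel()] or cohort simulation.
#'
#' @param path VCF file path.
#' @return A `haplotype_panel`.
#' @export
read_panel_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE))) {
    bad <- fix[grepl(",", fix[, "ALT"], fixed = TRUE), , drop = FALSE][1, ]
    stop("multiallelic record at position ", bad["POS"], " (", bad["ID"], ")")
  }
  gt <- vcf@gt[, -1, drop = FALSE]  # drop FORMAT column
  gt_dim <- dim(gt)
  gt <- sub(":.*$", "", gt)
  dim(gt) <- gt_dim
  unphased <- grepl("/", gt, fixed = TRUE)
  if (any(unphased)) {
    i <- (which(unphased)[1] - 1L) %% nrow(gt) + 1L
    stop("unphased genotype at position ", fix[i, "POS"], " (",
         fix[i, "ID"], "); phased GT (0|1) required")
  }
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  if (any(a1 %in% c(".", "") | a2 %in% c(".", "")))
    stop("missing genotypes are not supported in panel VCFs")
  M <- nrow(fix)
  n_ind <- ncol(gt)
  haps <- matrix(0L, 2 * n_ind, M)
  haps[seq(1, 2 * n_ind, 2), ] <- t(matrix(as.integer(a1), M, n_ind))
  haps[seq(2, 2 * n_ind, 2), ] <- t(matrix(as.integer(a2), M, n_ind))
  if (!all(haps %in% c(0L, 1L))) stop("non-biallelic genotype codes in VCF")
  meta <- vcf@meta
  popline <- grep("^##population=", meta, value = TRUE)
  population <- if (length(popline)) sub("^##population=", "", popline[1]) else "NA"
  rl <- grep("^##region_length=", meta, value = TRUE)
  region_length <- if (length(rl)) as.numeric(sub("^##region_length=", "", rl[1]))
                   else max(as.integer(fix[, "POS"]))
  info <- fix[, "INFO"]
  af <- suppressWarnings(as.numeric(sub("^.*AF=([0-9.eE+-]+).*$", "\\1", info)))
  freq <- colMeans(haps)
  af[is.na(af)] <- freq[is.na(af)]
  variants <- data.frame(
    id = fix[, "ID"], position = as.integer(fix[, "POS"]) - 1L,
    ref = fix[, "REF"], alt = fix[, "ALT"],
    ancestral_freq = pmin(pmax(af, 1e-9), 1 - 1e-9), freq = freq,
    is_coding = grepl("CODING", info, fixed = TRUE),
    stringsAsFactors = FALSE)
  new_haplotype_panel(population, variants, haps, region_length)
}
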