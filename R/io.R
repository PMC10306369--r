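# Real-data ingestion: phased VCF haplotypes, BED masks, observed-data
# summarisation with haplotype resampling, configuration and toy fixtures.
# Internal coordinates are 0-based half-open everywhere; conversions happen
# only at file boundaries (VCF is 1-based, BED is 0-based half-open).

#' Genomic region mask
#'
#' @param chrom,start,end vectors of intervals (0-based half-open).
#' @param mode `"exclude"` removes variants inside the intervals,
#'   `"include"` keeps only variants inside them.
#' @return A tibble of class `region_mask`, sorted and with overlapping
#'   intervals merged per chromosome.
#' @export
region_mask <- function(chrom, start, end, mode = c("exclude", "include")) {
  mode <- match.arg(mode)
  df <- tibble::tibble(chrom = as.character(chrom), start = start, end = end)
  if (any(df$end <= df$start)) stop("empty mask interval", call. = FALSE)
  df <- df |> dplyr::arrange(.data$chrom, .data$start)
  merged <- df |> dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(g, ...) {
      s <- g$start; e <- g$end
      ks <- numeric(0); ke <- numeric(0)
      for (i in seq_along(s)) {
        if (length(ks) && s[i] <= ke[length(ke)]) {
          ke[length(ke)] <- max(ke[length(ke)], e[i])
        } else {
          ks <- c(ks, s[i]); ke <- c(ke, e[i])
        }
      }
      tibble::tibble(start = ks, end = ke)
    }) |> dplyr::ungroup()
  attr(merged, "mode") <- mode
  class(merged) <- c("region_mask", class(merged))
  merged
}

#' Read a BED file as a region mask
#'
#' @param path BED file (chrom, start, end; 0-based half-open).
#' @param mode see [region_mask()].
#' @return A `region_mask`.
#' @export
read_bed <- function(path, mode = "exclude") {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  region_mask(bed[[1]], bed[[2]], bed[[3]], mode = mode)
}

#' Read phased haplotypes from a VCF
#'
#' Keeps biallelic SNPs only (multiallelic and indel records are dropped and
#' counted); REF is treated as the ancestral allele unless `aa_tag` names an
#' INFO tag carrying it. Phased diploid genotypes are split into two
#' haplotypes per sample (`sample_A`, `sample_B`); haploid genotypes are used
#' as is. Positions are converted from the VCF's 1-based coordinates to
#' 0-based coordinates relative to the region start.
#'
#' @param path VCF file (uncompressed or gzipped).
#' @param samples optional character vector of sample names to keep.
#' @param region optional list/tibble with `chrom`, `start`, `end` (0-based
#'   half-open) restricting the variants; its width sets `seq_length`.
#' @param seq_length chromosome length when no region is given (defaults to
#'   the last variant position + 1).
#' @param aa_tag optional INFO tag with the ancestral allele; variants whose
#'   tag matches ALT are polarity-flipped, variants matching neither allele
#'   are dropped.
#' @param force_haploidize split unphased diploid genotypes as if phased
#'   (otherwise unphased heterozygotes are an error).
#' @return A [haplotype_alignment()]; the number of dropped records is
#'   attached as attribute `n_dropped`.
#' @export
read_haplotypes <- function(path, samples = NULL, region = NULL,
                            seq_length = NULL, aa_tag = NULL,
                            force_haploidize = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  pos1 <- as.integer(fix[, "POS"])
  keep <- nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1 &
    !grepl(",", fix[, "ALT"], fixed = TRUE)
  offset <- 0
  if (!is.null(region)) {
    keep <- keep & fix[, "CHROM"] == region$chrom &
      pos1 - 1L >= region$start & pos1 - 1L < region$end
    offset <- region$start
    seq_length <- region$end - region$start
  }
  n_dropped <- sum(!keep)
  gt <- vcfR::extract.gt(v)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, colnames(v@gt)[-1]))
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(gt))
    if (length(missing))
      stop("samples not in VCF: ", paste(missing, collapse = ", "),
           call. = FALSE)
    gt <- gt[, samples, drop = FALSE]
  }
  gt <- gt[keep, , drop = FALSE]
  pos0 <- pos1[keep] - 1L - offset
  flip <- rep(FALSE, sum(keep))
  if (!is.null(aa_tag)) {
    aa <- vcfR::extract.info(v, element = aa_tag)[keep]
    ref <- fix[keep, "REF"]; alt <- fix[keep, "ALT"]
    bad <- !(aa %in% c(ref, alt)) | is.na(aa)
    flip <- aa == alt & !bad
    gt <- gt[!bad, , drop = FALSE]
    pos0 <- pos0[!bad]
    flip <- flip[!bad]
    n_dropped <- n_dropped + sum(bad)
  }
  # split genotype strings into haplotype rows
  diploid <- any(grepl("[|/]", gt))
  if (diploid) {
    if (any(grepl("/", gt, fixed = TRUE)) && !force_haploidize)
      stop("unphased diploid genotypes; set force_haploidize = TRUE to split",
           call. = FALSE)
    a1 <- substr(gt, 1, 1)
    a2 <- substr(gt, 3, 3)
    haps <- rbind(t(matrix(as.integer(a1), nrow = nrow(gt))),
                  t(matrix(as.integer(a2), nrow = nrow(gt))))
    ids <- c(paste0(colnames(gt), "_A"), paste0(colnames(gt), "_B"))
    ord <- order(rep(colnames(gt), 2), rep(c("A", "B"), each = ncol(gt)))
    haps <- haps[ord, , drop = FALSE]
    ids <- ids[ord]
  } else {
    haps <- t(matrix(as.integer(gt), nrow = nrow(gt)))
    ids <- colnames(gt)
  }
  if (any(flip)) haps[, flip] <- 1L - haps[, flip]
  if (is.null(seq_length))
    seq_length <- if (length(pos0)) max(pos0) + 1 else 1
  # enforce segregating, sorted, unique positions
  ord <- order(pos0)
  pos0 <- pos0[ord]; haps <- haps[, ord, drop = FALSE]
  dup <- duplicated(pos0)
  pos0 <- pos0[!dup]; haps <- haps[, !dup, drop = FALSE]
  aln <- haplotype_alignment(haps, pos0, seq_length, ids)
  attr(aln, "n_dropped") <- n_dropped
  aln
}

#' Apply a region mask to an alignment
#'
#' Removes variants falling in excluded intervals (or outside included ones)
#' and records the accessible length per window so that window diversity can
#' be compared fairly; windows below 50 percent accessibility are flagged.
#'
#' @param aln a [haplotype_alignment()].
#' @param mask a [region_mask()] (coordinates relative to the alignment).
#' @param window_size window size used for the accessibility record.
#' @return The masked alignment with attributes `accessible_length` and
#'   `window_accessibility` (tibble with `window`, `accessible`, `flagged`).
#' @export
apply_mask <- function(aln, mask, window_size = 10000) {
  stopifnot(inherits(aln, "haplotype_alignment"),
            inherits(mask, "region_mask"))
  mode <- attr(mask, "mode")
  L <- aln$seq_length
  inside <- rep(FALSE, length(aln$positions))
  cover <- rep(FALSE, max(1, ceiling(L)))
  for (i in seq_len(nrow(mask))) {
    a <- max(0, mask$start[i]); b <- min(L, mask$end[i])
    if (b <= a) next
    inside <- inside | (aln$positions >= a & aln$positions < b)
    cover[(a + 1):b] <- TRUE
  }
  keep <- if (mode == "exclude") !inside else inside
  acc_base <- if (mode == "exclude") !cover else cover
  aln2 <- haplotype_alignment(aln$geno[, keep, drop = FALSE],
                              aln$positions[keep], L, aln$sample_ids)
  n_win <- floor(L / window_size)
  win_acc <- if (n_win >= 1) {
    idx <- rep(seq_len(n_win), each = window_size)
    acc <- tapply(acc_base[seq_len(n_win * window_size)], idx, sum)
    tibble::tibble(window = seq_len(n_win), accessible = as.numeric(acc),
                   flagged = as.numeric(acc) < 0.5 * window_size)
  } else tibble::tibble(window = integer(0), accessible = numeric(0),
                        flagged = logical(0))
  attr(aln2, "accessible_length") <- sum(acc_base)
  attr(aln2, "window_accessibility") <- win_acc
  aln2
}

#' Summarise observed data with haplotype resampling
#'
#' Mirrors the observed-data protocol: draw `resample_size` haplotypes
#' without replacement `n_resample` times, compute the summary vector per
#' region and average across regions, yielding one summary vector per
#' resample. Class edges must be the frozen edges of the reference table the
#' observation will be compared against.
#'
#' @param alns list of per-region [haplotype_alignment()]s (same haplotype
#'   panel in each).
#' @param class_edges frozen diversity-class edges.
#' @param n_resample number of resampling rounds.
#' @param resample_size haplotypes per round (default 12).
#' @param spec summary set.
#' @param window_size TM_win window size.
#' @param seed optional integer seed.
#' @return A list of named summary vectors, one per resample.
#' @export
observed_summaries <- function(alns, class_edges, n_resample = 10,
                               resample_size = 12, spec = "all",
                               window_size = 10000, seed = NULL) {
  if (!length(alns)) stop("no regions given", call. = FALSE)
  n_hap <- nrow(alns[[1]]$geno)
  if (resample_size > n_hap)
    stop("fewer haplotypes than the resample size", call. = FALSE)
  .with_seed(seed, {
    lapply(seq_len(n_resample), function(i) {
      take <- sort(sample.int(n_hap, resample_size))
      combine_loci(lapply(alns, function(a) {
        sub <- haplotype_alignment(a$geno[take, , drop = FALSE],
                                   a$positions, a$seq_length,
                                   a$sample_ids[take])
        seg <- colSums(sub$geno)
        keep <- seg > 0 & seg < resample_size
        sub <- haplotype_alignment(sub$geno[, keep, drop = FALSE],
                                   sub$positions[keep], sub$seq_length,
                                   sub$sample_ids)
        summary_vector(sub, spec = spec, class_edges = class_edges,
                       window_size = window_size)
      }))
    })
  })
}

#' Write a minimal VCF for a haplotype alignment
#'
#' Haploid GT columns, ancestral allele as REF (`A`), derived as ALT (`T`);
#' positions converted to 1-based.
#'
#' @param aln a [haplotype_alignment()].
#' @param path output file.
#' @param chrom chromosome name.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(aln, path, chrom = "chr1") {
  stopifnot(inherits(aln, "haplotype_alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", chrom,
                       as.integer(aln$seq_length)),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", aln$sample_ids), collapse = "\t")),
             con)
  if (ncol(aln$geno)) {
    body <- vapply(seq_along(aln$positions), function(j) {
      paste(c(chrom, aln$positions[j] + 1L, ".", "A", "T", ".", "PASS", ".",
              "GT", aln$geno[, j]), collapse = "\t")
    }, character(1))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read or write a dataset configuration
#'
#' YAML with the scenario, simulation dimensions and analysis settings; the
#' scenario keys are `N_pres`, `N_anc`, `t_N`, `sigma_pres`, `sigma_anc`,
#' `t_sigma`, `rec_rate`, `mut_rate`.
#'
#' @param path YAML file.
#' @return For `read_config`, a list with a `transition_scenario` under
#'   `$scenario` plus any further entries.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$scenario))
    cfg$scenario <- do.call(transition_scenario, cfg$scenario)
  cfg
}

#' @rdname read_config
#' @param config list to write; a `transition_scenario` under `$scenario` is
#'   flattened to its keys.
#' @export
write_config <- function(config, path) {
  if (inherits(config$scenario, "transition_scenario"))
    config$scenario <- unclass(config$scenario)
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Preset for a reference Arabidopsis thaliana analysis
#'
#' Mutation rate 6.95e-9, recombination rate 3.6e-9 per site per generation,
#' 12 resampled haplotypes over five 1-Mb regions, 20 PLS components.
#'
#' @return A list of defaults for analysing real data.
#' @export
athaliana_preset <- function() {
  list(mut_rate = 6.95e-9, rec_rate = 3.6e-9, resample_size = 12,
       n_regions = 5, region_length = 1e6, n_pls = 20,
       window_size = 10000, tolerance = 0.01)
}

#' Write a deterministic toy fixture
#'
#' Simulates a small documented transition scenario (20 haplotypes, 100 kb),
#' writes the VCF, a BED mask, a YAML config and the expected summary TSV.
#' Identical seeds give byte-identical directories.
#'
#' @param dir output directory.
#' @param seed integer seed (mandatory).
#' @return `dir`, invisibly.
#' @export
make_fixture <- function(dir, seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sc <- transition_scenario(N_pres = 10000, N_anc = 10000, t_N = 0,
                            sigma_pres = 0.95, sigma_anc = 0, t_sigma = 20000,
                            rec_rate = 1e-8, mut_rate = 1e-8)
  aln <- .with_seed(seed,
    simulate_sample(sc, n = 20, L = 1e5, mu = sc$mut_rate)$alignment)
  write_vcf(aln, file.path(dir, "toy.vcf"))
  writeLines(c("chr1\t40000\t45000"), file.path(dir, "mask.bed"))
  write_config(list(scenario = sc, n_hap = 20, L = 1e5, seed = seed,
                    window_size = 10000),
               file.path(dir, "config.yaml"))
  edges <- c(1, 2, 3, 5, 8, 12, 17)
  sv <- .with_seed(seed,
    summary_vector(aln, spec = "all", class_edges = edges))
  df <- as.data.frame(t(sv))
  utils::write.table(format(df, digits = 15), file.path(dir, "expected_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
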