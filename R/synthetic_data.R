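#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. Defaults reproduce the
#' study design the package targets - 6 case (PA-E) vs 5 control (CTR)
#' libraries - at a desk-scale fixture size of 2,000 genes, 300 splicing
#' events and 3,000 allele sites. Planted effects default to log2 fold
#' changes of mean 2 (random sign), group PSI differences of 0.3 and
#' group allele-fraction differences of 0.5; NB dispersions are
#' gamma-distributed with mean 0.1 and library-size factors log-normal
#' with sdlog 0.2.
#'
#' @param seed Integer master seed; each stage derives its own stream
#'   deterministically from it.
#' @param n_case,n_ctrl Group sizes (>= 2).
#' @param n_genes,frac_de,log2fc_mean,log2fc_sd Count-simulation shape:
#'   number of genes, fraction differentially expressed, magnitude
#'   distribution of planted log2 fold changes.
#' @param disp_shape,disp_rate Gamma parameters of per-gene NB dispersion.
#' @param libsize_sd sdlog of the log-normal library-size factors.
#' @param mean_log_mu,sd_log_mu Log-normal distribution of baseline gene
#'   expression.
#' @param frac_lnc_genes Fraction of genes hosting lncRNA transcripts.
#' @param n_links Number of planted lncRNA-mRNA co-expression links.
#' @param n_events,frac_das,dpsi,junction_coverage Splicing simulation:
#'   events (split evenly over SE/RI/A3SS/A5SS/MXE), fraction with a
#'   planted PSI shift of `dpsi`, mean junction coverage per sample.
#' @param n_sites,frac_ase,daaf,depth_mean,frac_masked Allele-count
#'   simulation: sites, fraction with a planted AAF shift of `daaf`,
#'   Poisson mean depth, fraction of sites placed inside mask regions
#'   (split evenly over the four classes).
#' @param n_transcripts,frac_noncoding Transcript-sequence simulation.
#' @param n_qpcr_genes,qpcr_e,cq_sd,n_tech qPCR simulation: number of
#'   target genes, amplification efficiency, Cq replicate noise SD,
#'   technical replicates per biological sample.
#' @param n_model_genes Genes covered by the synthetic genome and GTF.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_case = 6L, n_ctrl = 5L,
                       n_genes = 2000L, frac_de = 0.1,
                       log2fc_mean = 2, log2fc_sd = 0.5,
                       disp_shape = 2, disp_rate = 20,
                       libsize_sd = 0.2,
                       mean_log_mu = log(50), sd_log_mu = 1.5,
                       frac_lnc_genes = 0.1, n_links = 40L,
                       n_events = 300L, frac_das = 0.2, dpsi = 0.3,
                       junction_coverage = 100,
                       n_sites = 3000L, frac_ase = 0.1, daaf = 0.5,
                       depth_mean = 50, frac_masked = 0.08,
                       n_transcripts = 500L, frac_noncoding = 0.5,
                       n_qpcr_genes = 12L, qpcr_e = 2, cq_sd = 0.1,
                       n_tech = 4L,
                       n_model_genes = 150L) {
  stopifnot(n_case >= 2L, n_ctrl >= 2L,
            frac_de >= 0, frac_de <= 1, frac_das >= 0, frac_das <= 1,
            frac_ase >= 0, frac_ase <= 1, frac_masked >= 0, frac_masked <= 1,
            frac_noncoding >= 0, frac_noncoding <= 1,
            dpsi >= 0, dpsi <= 1, daaf >= 0, daaf <= 1,
            qpcr_e > 1, qpcr_e <= 2.2, cq_sd >= 0)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic per-stage RNG streams derived from the master seed.
stage_seed <- function(cfg, stage) {
  offsets <- c(counts = 101L, junctions = 202L, alleles = 303L,
               transcripts = 404L, qpcr = 505L, genome = 606L, maps = 707L)
  set.seed((cfg$seed %% 1000000L) * 1000L + offsets[[stage]])
}

#' Study design implied by a simulation configuration
#'
#' @param cfg A [sim_config].
#' @return A [sample_design] with `n_case` PA-E and `n_ctrl` CTR samples.
#' @export
sim_design <- function(cfg) {
  sample_design(c(paste0("PA-E", seq_len(cfg$n_case)),
                  paste0("CTR", seq_len(cfg$n_ctrl))),
                c(rep("PA-E", cfg$n_case), rep("CTR", cfg$n_ctrl)))
}

#' Simulate an NB count matrix with planted fold changes
#'
#' Counts are NB with mean \eqn{s_j q_{gi}} and gene dispersion
#' \eqn{\alpha_g}; in the case group \eqn{q} is multiplied by
#' \eqn{2^{log2FC}} for DE genes. A subset of genes is tagged as lncRNA
#' hosts, and planted lncRNA-mRNA co-expression links couple the lncRNA
#' counts to their partner's realised expression (positive or negative).
#'
#' @param cfg A [sim_config].
#' @return list with `counts`, `design`, `truth` (per-gene `is_de`,
#'   `log2fc`, `is_lnc`, `dispersion`, `base_mean`), `size_factors` and
#'   `links` (planted lncRNA-mRNA pairs with true sign).
#' @export
simulate_counts <- function(cfg = sim_config()) {
  stage_seed(cfg, "counts")
  design <- sim_design(cfg)
  n <- cfg$n_genes
  ids <- sprintf("G%04d", seq_len(n))
  q <- exp(stats::rnorm(n, cfg$mean_log_mu, cfg$sd_log_mu))
  alpha <- stats::rgamma(n, shape = cfg$disp_shape, rate = cfg$disp_rate)
  s <- exp(stats::rnorm(nrow(design), 0, cfg$libsize_sd))
  is_lnc <- seq_len(n) %in% sample.int(n, round(cfg$frac_lnc_genes * n))
  is_de <- seq_len(n) %in% sample.int(n, round(cfg$frac_de * n))
  lfc <- rep(0, n)
  lfc[is_de] <- sample(c(-1, 1), sum(is_de), TRUE) *
    abs(stats::rnorm(sum(is_de), cfg$log2fc_mean, cfg$log2fc_sd))
  is_case <- design$group == attr(design, "case")
  mu <- outer(q, s)
  mu[, is_case] <- mu[, is_case] * 2^lfc
  counts <- matrix(stats::rnbinom(n * nrow(design), mu = mu,
                                  size = 1 / pmax(alpha, 1e-8)),
                   nrow = n, dimnames = list(ids, design$sample_id))
  ## planted trans links: lncRNA counts re-drawn around the partner's
  ## realised (normalised) profile with low dispersion
  lnc_pool <- which(is_lnc)
  cod_pool <- which(!is_lnc)
  n_links <- min(cfg$n_links, length(lnc_pool), length(cod_pool))
  links <- NULL
  if (n_links > 0) {
    la <- sample(lnc_pool, n_links)
    pa <- sample(cod_pool, n_links)
    sgn <- sample(c("positive", "negative"), n_links, TRUE,
                  prob = c(0.9, 0.1))
    for (i in seq_len(n_links)) {
      partner_rel <- (counts[pa[i], ] / s + 0.5) / (q[pa[i]] + 0.5)
      coupling <- if (sgn[i] == "positive") partner_rel else 1 / partner_rel
      mu_l <- pmax(q[la[i]] * coupling * s, 0.05)
      counts[la[i], ] <- stats::rnbinom(length(mu_l), mu = mu_l,
                                        size = 1 / 0.005)
    }
    links <- data.frame(lnc_gene = ids[la], partner_gene = ids[pa],
                        sign = sgn, stringsAsFactors = FALSE)
  }
  truth <- data.frame(gene_id = ids, is_de = is_de, log2fc = lfc,
                      is_lnc = is_lnc, dispersion = alpha, base_mean = q,
                      stringsAsFactors = FALSE)
  list(counts = counts, design = design, truth = truth,
       size_factors = s, links = links)
}

event_lengths <- function(type, u = junction_positions()) {
  l_inc <- c(SE = 2L, RI = 2L, A3SS = 1L, A5SS = 1L, MXE = 2L)[type] * u
  l_skip <- c(SE = 1L, RI = 1L, A3SS = 1L, A5SS = 1L, MXE = 2L)[type] * u
  cbind(l_inc = unname(l_inc), l_skip = unname(l_skip))
}

#' Simulate junction counts at planted PSI
#'
#' Per event and sample, total junction-read coverage is Poisson and the
#' inclusion count is binomial with probability
#' \eqn{\psi l_I / (\psi l_I + (1-\psi) l_S)}; the skipping count is the
#' remainder. Zero coverage is allowed and yields NA PSI downstream.
#'
#' @param cfg A [sim_config].
#' @param gene_ids Optional pool of gene ids to attach events to.
#' @return list with `events`, `junctions` (long table) and `truth`
#'   (per-event planted PSI pair and `is_das`).
#' @export
simulate_junctions <- function(cfg = sim_config(), gene_ids = NULL) {
  stage_seed(cfg, "junctions")
  design <- sim_design(cfg)
  types <- rep(c("SE", "RI", "A3SS", "A5SS", "MXE"),
               length.out = cfg$n_events)
  if (is.null(gene_ids)) gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  ev_gene <- sample(gene_ids, cfg$n_events, replace = TRUE)
  L <- event_lengths(types)
  psi_ctrl <- stats::runif(cfg$n_events, 0.15, 0.85)
  is_das <- seq_len(cfg$n_events) %in%
    sample.int(cfg$n_events, round(cfg$frac_das * cfg$n_events))
  shift <- ifelse(psi_ctrl < 0.5, cfg$dpsi, -cfg$dpsi)
  psi_case <- ifelse(is_das, pmin(pmax(psi_ctrl + shift, 0.02), 0.98),
                     psi_ctrl)
  events <- data.frame(event_id = sprintf("SIM_EV%05d", seq_len(cfg$n_events)),
                       gene_id = ev_gene, type = types,
                       chrom = "chrSIM", strand = "+",
                       inclusion_form = ".", skipping_form = ".",
                       l_inc = L[, "l_inc"], l_skip = L[, "l_skip"],
                       stringsAsFactors = FALSE)
  is_case <- design$group == attr(design, "case")
  rows <- vector("list", cfg$n_events)
  for (e in seq_len(cfg$n_events)) {
    psi <- ifelse(is_case, psi_case[e], psi_ctrl[e])
    theta <- psi * L[e, "l_inc"] /
      (psi * L[e, "l_inc"] + (1 - psi) * L[e, "l_skip"])
    n <- stats::rpois(nrow(design), cfg$junction_coverage)
    I <- stats::rbinom(nrow(design), n, theta)
    rows[[e]] <- data.frame(event_id = events$event_id[e],
                            sample_id = design$sample_id,
                            inclusion = I, skipping = n - I,
                            stringsAsFactors = FALSE)
  }
  truth <- data.frame(event_id = events$event_id, type = types,
                      psi_case = psi_case, psi_ctrl = psi_ctrl,
                      is_das = is_das, stringsAsFactors = FALSE)
  list(events = events, junctions = do.call(rbind, rows), truth = truth)
}

#' Simulate per-site allele counts at planted allele fractions
#'
#' Depth is Poisson (floor 1); alternative counts are binomial at the
#' group's planted AAF. A configured fraction of sites is placed inside
#' each region-mask class (SSR, pseudogene, bidirectional, intron-flank),
#' drawn from supplied masks when given, otherwise from generated
#' interval sets on a virtual chromosome.
#'
#' @param cfg A [sim_config].
#' @param masks Optional named list of `GRanges` (classes as in
#'   [build_region_mask()]) to place masked sites into.
#' @param genome Optional genome (sites then take their reference base
#'   from it).
#' @return list with `sites` (an [allele_sites]), `truth` (planted AAF
#'   pair, significance flag, mask class) and `masks` (the mask set used).
#' @export
simulate_allele_counts <- function(cfg = sim_config(), masks = NULL,
                                   genome = NULL) {
  stage_seed(cfg, "alleles")
  design <- sim_design(cfg)
  n <- cfg$n_sites
  classes <- c("bidirectional", "intron_flank", "ssr", "pseudogene")
  if (is.null(masks)) {
    # virtual chromosome with disjoint mask intervals per class
    starts <- seq(10000L, by = 5000L, length.out = 40L)
    masks <- list()
    for (ci in seq_along(classes)) {
      s <- starts[seq(ci, 40L, by = 4L)]
      masks[[classes[ci]]] <- GenomicRanges::GRanges(
        "chrV", IRanges::IRanges(s, s + 199L))
    }
    chrom_len <- 500000L
    chroms <- "chrV"
  } else {
    chroms <- unique(unlist(lapply(masks, function(m)
      as.character(GenomicRanges::seqnames(m)))))
    if (!is.null(genome)) chroms <- names(genome)
    chrom_len <- if (!is.null(genome))
      stats::setNames(nchar(genome), names(genome)) else
        stats::setNames(rep(500000L, length(chroms)), chroms)
  }
  n_masked_per <- round(cfg$frac_masked * n / length(classes))
  truth_class <- rep("none", n)
  chrom <- character(n); pos <- integer(n)
  all_mask <- GenomicRanges::reduce(do.call(c, unname(masks)))
  i <- 1L
  for (ci in seq_along(classes)) {
    m <- masks[[classes[ci]]]
    if (length(m) == 0L || n_masked_per == 0L) next
    take <- min(n_masked_per, n - i + 1L)
    pick <- sample(length(m), take, replace = TRUE)
    p <- GenomicRanges::start(m)[pick] +
      floor(stats::runif(take) * IRanges::width(m)[pick])
    chrom[i:(i + take - 1L)] <- as.character(GenomicRanges::seqnames(m))[pick]
    pos[i:(i + take - 1L)] <- as.integer(p)
    truth_class[i:(i + take - 1L)] <- classes[ci]
    i <- i + take
  }
  # unmasked sites: rejection-sample positions outside every mask
  while (i <= n) {
    k <- n - i + 1L
    cc <- sample(chroms, k, replace = TRUE)
    len <- if (length(chrom_len) == 1L) rep(chrom_len, k) else chrom_len[cc]
    pp <- 1L + floor(stats::runif(k) * len)
    cand <- GenomicRanges::GRanges(cc, IRanges::IRanges(pp, pp))
    ok <- !IRanges::overlapsAny(cand, all_mask)
    if (!any(ok)) next
    idx <- i:(i + sum(ok) - 1L)
    chrom[idx] <- cc[ok]; pos[idx] <- as.integer(pp[ok])
    i <- i + sum(ok)
  }
  bases <- c("A", "C", "G", "T")
  ref <- if (!is.null(genome))
    substring(genome[chrom], pos, pos) else sample(bases, n, TRUE)
  ref[!ref %in% bases] <- "A"
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  aaf_ctrl <- stats::runif(n, 0.05, 0.95)
  is_ase <- seq_len(n) %in% sample.int(n, round(cfg$frac_ase * n))
  aaf_case <- aaf_ctrl
  if (any(is_ase)) {
    # draw the lower of the two fractions so the planted difference is
    # exactly daaf, direction random
    k <- sum(is_ase)
    lower <- stats::runif(k, 0.01, max(0.99 - cfg$daaf, 0.01))
    up <- stats::runif(k) < 0.5
    aaf_ctrl[is_ase] <- ifelse(up, lower, lower + cfg$daaf)
    aaf_case[is_ase] <- ifelse(up, lower + cfg$daaf, lower)
  }
  is_case <- design$group == attr(design, "case")
  depth <- matrix(pmax(stats::rpois(n * nrow(design), cfg$depth_mean), 1L),
                  nrow = n)
  aaf_mat <- matrix(rep(aaf_ctrl, nrow(design)), nrow = n)
  aaf_mat[, is_case] <- aaf_case
  altc <- matrix(stats::rbinom(length(depth), depth, aaf_mat), nrow = n)
  refc <- depth - altc
  colnames(refc) <- colnames(altc) <- design$sample_id
  sites <- data.frame(chrom = chrom, pos = pos,
                      id = ifelse(stats::runif(n) < 0.5,
                                  sprintf("rs%07d", seq_len(n)), "."),
                      ref = unname(ref), alt = unname(alt),
                      stringsAsFactors = FALSE)
  x <- allele_sites(sites, refc, altc)
  truth <- data.frame(chrom = chrom, pos = pos,
                      aaf_case = aaf_case, aaf_ctrl = aaf_ctrl,
                      is_ase = is_ase, mask_class = truth_class,
                      stringsAsFactors = FALSE)
  list(sites = x, truth = truth, masks = masks)
}

sample_from_composition <- function(n, base_p) {
  paste(sample(names(base_p), n, TRUE, prob = base_p), collapse = "")
}

#' Simulate coding and noncoding transcript sequences
#'
#' Coding transcripts carry an ATG..stop ORF of at least 100 codons drawn
#' from the package codon-usage model between composition-matched UTRs;
#' noncoding transcripts are composition-matched random sequence with any
#' ORF shorter than 300 nt enforced by rejection (error after 1,000
#' tries). Rfam/Pfam homology flags are FALSE for all planted lncRNAs
#' and TRUE with probability 0.6 for coding transcripts.
#'
#' @param cfg A [sim_config].
#' @return list with `records` (data.frame `transcript_id, sequence,
#'   exon_count, rfam_hit, pfam_hit`) and `truth` (`is_noncoding`).
#' @export
simulate_transcript_sequences <- function(cfg = sim_config()) {
  stage_seed(cfg, "transcripts")
  bg <- hexamer_background()
  base_p <- bg$base_p
  usage <- codon_usage()
  codons <- names(usage)
  stops <- c("TAA", "TAG", "TGA")
  n <- cfg$n_transcripts
  is_nc <- seq_len(n) %in% sample.int(n, round(cfg$frac_noncoding * n))
  seqs <- character(n)
  for (i in seq_len(n)) {
    len <- sample(400:1500, 1L)
    if (!is_nc[i]) {
      n_codons <- max(100L, (round(len * 0.6) %/% 3L))
      body <- sample(codons, n_codons - 2L, TRUE, prob = usage)
      orf <- paste0("ATG", paste(body, collapse = ""), sample(stops, 1L))
      rest <- len - nchar(orf)
      u5 <- max(10L, rest %/% 2L); u3 <- max(10L, rest - u5)
      seqs[i] <- paste0(sample_from_composition(u5, base_p), orf,
                        sample_from_composition(u3, base_p))
    } else {
      ok <- FALSE
      for (try in seq_len(1000L)) {
        s <- sample_from_composition(len, base_p)
        if (longest_orf(s)$length < 300L) { ok <- TRUE; break }
      }
      if (!ok) stop("rejection cap reached while sampling a noncoding ",
                    "sequence of length ", len)
      seqs[i] <- s
    }
  }
  records <- data.frame(
    transcript_id = sprintf("TX%04d", seq_len(n)),
    sequence = seqs,
    exon_count = sample(2:5, n, TRUE),
    rfam_hit = !is_nc & stats::runif(n) < 0.6,
    pfam_hit = !is_nc & stats::runif(n) < 0.6,
    stringsAsFactors = FALSE)
  truth <- data.frame(transcript_id = records$transcript_id,
                      is_noncoding = is_nc, stringsAsFactors = FALSE)
  list(records = records, truth = truth)
}

#' Simulate a qPCR Cq table under an efficiency model
#'
#' Cq = Cq0 - log_E(concentration) + Normal(0, sd), four technical
#' replicates per biological sample; target-gene concentration in the
#' case group equals the planted fold change, reference genes (ACTB,
#' GAPDH) stay at fold change 1.
#'
#' @param cfg A [sim_config].
#' @param fold_changes Optional named per-gene fold changes (case over
#'   control); default: `n_qpcr_genes` genes alternating 2 and 0.5.
#' @return list with `cq` (long table) and `truth` (per-gene fold change).
#' @export
simulate_qpcr <- function(cfg = sim_config(), fold_changes = NULL) {
  stage_seed(cfg, "qpcr")
  design <- sim_design(cfg)
  if (is.null(fold_changes)) {
    fold_changes <- stats::setNames(
      rep(c(2, 0.5), length.out = cfg$n_qpcr_genes),
      sprintf("Q%02d", seq_len(cfg$n_qpcr_genes)))
  }
  genes <- c(names(fold_changes), "ACTB", "GAPDH")
  fc <- c(fold_changes, ACTB = 1, GAPDH = 1)
  is_case <- design$group == attr(design, "case")
  rows <- list()
  for (g in genes) {
    cq0 <- stats::runif(1, 20, 26)
    conc <- ifelse(is_case, fc[[g]], 1)
    for (si in seq_len(nrow(design))) {
      cq_mean <- cq0 - log(conc[si], base = cfg$qpcr_e)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, sample_id = design$sample_id[si],
        group = design$group[si], replicate = seq_len(cfg$n_tech),
        cq = cq_mean + stats::rnorm(cfg$n_tech, 0, cfg$cq_sd),
        stringsAsFactors = FALSE)
    }
  }
  list(cq = do.call(rbind, rows),
       truth = data.frame(gene = names(fold_changes),
                          fold_change = unname(fold_changes),
                          stringsAsFactors = FALSE))
}
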