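#' Simulation configuration for paired genome/transcriptome cohorts
#'
#' Bundles every parameter of the synthetic cohort generator: a two-group
#' (non-metastatic primary vs nodal metastasis) SNP-array cohort with
#' segmental copy-number gains/losses, an expression matrix in which planted
#' driver transcripts respond linearly to local copy number, a survival table
#' with two competing causes of death, and an siRNA viability screen with
#' planted growth-suppression effects.
#'
#' The defaults describe the reference study conditions used throughout the
#' package's validation experiments: 20 + 20 samples, four chromosomes of
#' 100 SNPs at 100 kb spacing, metastasis-specific segments of 30 SNPs at
#' log2 shift +/-0.5 against array noise of SD 0.15, and 1000 transcripts of
#' which 40 are copy-number drivers (beta = 1.5 expression units per unit
#' log2 copy number) and 40 are differentially expressed without a
#' copy-number link.
#'
#' @param n_primary,n_met number of non-metastatic primary / metastatic
#'   samples.
#' @param n_chrom,snps_per_chrom,snp_spacing_bp SNP panel geometry.
#' @param segment_map data.frame with columns \code{chrom} (integer index),
#'   \code{start_snp}, \code{end_snp} (1-based SNP indices within the
#'   chromosome, inclusive), \code{group} (\code{"primary"}, \code{"met"} or
#'   \code{"both"}), \code{shift} (mean log2-ratio shift). Segments for the
#'   same group on one chromosome must not overlap.
#' @param noise_sd_cn SD of additive Gaussian noise on log2 ratios.
#' @param n_transcripts,n_drivers,n_de_only transcript counts; drivers are
#'   placed inside group-differential segments, DE-only and null transcripts
#'   are placed so their cis windows avoid differential segments.
#' @param driver_beta expression units per unit log2 copy number for driver
#'   transcripts.
#' @param de_nondriver_effect log2 expression shift (metastatic minus
#'   primary) for DE-only transcripts.
#' @param noise_sd_expr SD of additive Gaussian expression noise.
#' @param baseline_expr_mean,baseline_expr_sd distribution of per-transcript
#'   baseline log2 expression.
#' @param window_bp cis-window half-width used when placing non-driver
#'   transcripts clear of differential segments (matches the analysis
#'   window).
#' @param hazard_disease,hazard_other length-2 vectors of cause-specific
#'   exponential hazards (per year) for clusters 1 and 2.
#' @param hazard_censor exponential censoring hazard (0 = no censoring).
#' @param n_signature_genes,n_background_genes,n_lines,n_replicates screen
#'   geometry.
#' @param n_hits_signature,n_hits_background number of genes planted with a
#'   growth-suppression effect in each set.
#' @param hit_viability,nonhit_viability true relative viability of the
#'   affected line of planted hits, and of all other gene/line combinations.
#' @param replicate_cv coefficient of variation of multiplicative lognormal
#'   replicate noise.
#' @param suppression_effects optional gene x cell-line matrix of true
#'   relative viabilities overriding the planted two-level default map.
#' @param seed integer master seed; each generator draws from its own
#'   substream so stages are independently reproducible.
#' @return object of class \code{"sim_config"} (a validated list).
#' @export
sim_config <- function(n_primary = 20, n_met = 20,
                       n_chrom = 4, snps_per_chrom = 100,
                       snp_spacing_bp = 100000,
                       segment_map = default_segment_map(),
                       noise_sd_cn = 0.15,
                       n_transcripts = 1000, n_drivers = 40, n_de_only = 40,
                       driver_beta = 1.5, de_nondriver_effect = 1.0,
                       noise_sd_expr = 0.35,
                       baseline_expr_mean = 7, baseline_expr_sd = 1,
                       window_bp = 250000,
                       hazard_disease = c(0.04, 0.19),
                       hazard_other = c(0.03, 0.03),
                       hazard_censor = 0.05,
                       n_signature_genes = 26, n_background_genes = 708,
                       n_lines = 5, n_replicates = 9,
                       n_hits_signature = 18, n_hits_background = 149,
                       hit_viability = 0.55, nonhit_viability = 0.92,
                       replicate_cv = 0.10,
                       suppression_effects = NULL,
                       seed = 1) {
  counts <- c(n_primary = n_primary, n_met = n_met, n_chrom = n_chrom,
              snps_per_chrom = snps_per_chrom, snp_spacing_bp = snp_spacing_bp,
              n_transcripts = n_transcripts,
              n_lines = n_lines, n_replicates = n_replicates,
              n_signature_genes = n_signature_genes,
              n_background_genes = n_background_genes)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (n_drivers < 0 || n_de_only < 0) stop("driver/DE-only counts must be >= 0")
  if (n_drivers + n_de_only > n_transcripts)
    stop("n_drivers + n_de_only exceeds n_transcripts")
  sds <- c(noise_sd_cn, noise_sd_expr, baseline_expr_sd, replicate_cv)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (any(hazard_disease <= 0) || any(hazard_other <= 0))
    stop("cause-specific hazards must be positive")
  if (hazard_censor < 0) stop("censoring hazard must be >= 0")
  if (hit_viability < 0 || nonhit_viability < 0)
    stop("viability effects must be non-negative")
  if (n_hits_signature > n_signature_genes ||
      n_hits_background > n_background_genes)
    stop("planted hit counts exceed set sizes")
  if (!is.null(suppression_effects)) {
    if (!is.matrix(suppression_effects) || is.null(rownames(suppression_effects)))
      stop("suppression_effects must be a gene x line matrix with rownames")
    if (any(suppression_effects < 0))
      stop("viability effects must be non-negative")
    if (ncol(suppression_effects) != n_lines)
      stop("suppression_effects must have one column per cell line")
  }
  segment_map <- validate_segment_map(segment_map, n_chrom, snps_per_chrom)
  cfg <- list(n_primary = n_primary, n_met = n_met, n_chrom = n_chrom,
              snps_per_chrom = snps_per_chrom, snp_spacing_bp = snp_spacing_bp,
              segment_map = segment_map, noise_sd_cn = noise_sd_cn,
              n_transcripts = n_transcripts, n_drivers = n_drivers,
              n_de_only = n_de_only, driver_beta = driver_beta,
              de_nondriver_effect = de_nondriver_effect,
              noise_sd_expr = noise_sd_expr,
              baseline_expr_mean = baseline_expr_mean,
              baseline_expr_sd = baseline_expr_sd,
              window_bp = window_bp,
              hazard_disease = hazard_disease, hazard_other = hazard_other,
              hazard_censor = hazard_censor,
              n_signature_genes = n_signature_genes,
              n_background_genes = n_background_genes,
              n_lines = n_lines, n_replicates = n_replicates,
              n_hits_signature = n_hits_signature,
              n_hits_background = n_hits_background,
              hit_viability = hit_viability,
              nonhit_viability = nonhit_viability,
              replicate_cv = replicate_cv,
              suppression_effects = suppression_effects,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Default segmental copy-number architecture
#'
#' Four metastasis-specific segments (two gains, two losses, 30 SNPs each at
#' log2 shift +/-0.5), one primary-specific loss, and one shared gain carried
#' by both groups.
#'
#' @return data.frame with columns chrom, start_snp, end_snp, group, shift.
#' @export
default_segment_map <- function() {
  data.frame(
    chrom     = c(1L, 2L, 3L, 4L, 3L, 2L),
    start_snp = c(21L, 11L, 51L, 31L, 11L, 61L),
    end_snp   = c(50L, 40L, 80L, 60L, 30L, 85L),
    group     = c("met", "met", "met", "met", "primary", "both"),
    shift     = c(0.5, -0.5, 0.5, -0.5, -0.4, 0.4),
    stringsAsFactors = FALSE
  )
}

validate_segment_map <- function(seg, n_chrom, snps_per_chrom) {
  if (is.null(seg) || nrow(seg) == 0L)
    return(data.frame(chrom = integer(), start_snp = integer(),
                      end_snp = integer(), group = character(),
                      shift = numeric(), stringsAsFactors = FALSE))
  need <- c("chrom", "start_snp", "end_snp", "group", "shift")
  if (!all(need %in% names(seg))) stop("segment_map missing columns")
  if (!all(seg$group %in% c("primary", "met", "both")))
    stop("segment group must be 'primary', 'met' or 'both'")
  if (any(seg$chrom < 1 | seg$chrom > n_chrom)) stop("segment chrom out of range")
  if (any(seg$start_snp < 1 | seg$end_snp > snps_per_chrom |
          seg$start_snp > seg$end_snp))
    stop("segment SNP indices out of range")
  # a 'both' segment occupies both groups' tracks
  for (g in c("primary", "met")) {
    sub <- seg[seg$group %in% c(g, "both"), , drop = FALSE]
    for (ch in unique(sub$chrom)) {
      s <- sub[sub$chrom == ch, , drop = FALSE]
      s <- s[order(s$start_snp), , drop = FALSE]
      if (nrow(s) > 1L && any(s$start_snp[-1L] <= s$end_snp[-nrow(s)]))
        stop("overlapping segments on chromosome ", ch, " for group ", g)
    }
  }
  seg
}

# deterministic per-stage substream seeds derived from the master seed
stream_seed <- function(seed, stage) {
  stages <- c(genomes = 1L, expression = 2L, survival = 3L, screen = 4L)
  (abs(as.integer(seed)) %% 2146489L) * 1000L + stages[[stage]]
}

# per-SNP true mean log2 shift for one group ("primary" or "met")
true_shift_track <- function(config, group) {
  shift <- numeric(config$n_chrom * config$snps_per_chrom)
  seg <- config$segment_map
  if (nrow(seg) == 0L) return(shift)
  seg <- seg[seg$group %in% c(group, "both"), , drop = FALSE]
  for (i in seq_len(nrow(seg))) {
    off <- (seg$chrom[i] - 1L) * config$snps_per_chrom
    idx <- (off + seg$start_snp[i]):(off + seg$end_snp[i])
    shift[idx] <- shift[idx] + seg$shift[i]
  }
  shift
}

#' Generate a synthetic SNP-array cohort
#'
#' Emits a SNP panel with strictly increasing positions per chromosome and a
#' probes x samples matrix of log2 tumor:reference intensity ratios: the
#' group-specific segment shift plus Gaussian noise. Sample columns are
#' primary samples first, then metastatic.
#'
#' @param config a [sim_config()] object.
#' @return list with elements \code{panel} (data.frame: probe_id, chrom,
#'   pos), \code{cn} (matrix, probes x samples), \code{samples} (data.frame:
#'   sample_id, group), and \code{truth} (list with the segment map and
#'   per-group true shift tracks).
#' @export
generate_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config$seed, "genomes"))
  n_snp <- config$n_chrom * config$snps_per_chrom
  chrom <- rep(seq_len(config$n_chrom), each = config$snps_per_chrom)
  pos <- rep(seq_len(config$snps_per_chrom), times = config$n_chrom) *
    config$snp_spacing_bp
  panel <- data.frame(
    probe_id = sprintf("snp_%d_%04d", chrom,
                       rep(seq_len(config$snps_per_chrom), config$n_chrom)),
    chrom = paste0("chr", chrom),
    pos = as.integer(pos),
    stringsAsFactors = FALSE
  )
  groups <- c(rep("primary", config$n_primary), rep("met", config$n_met))
  samples <- data.frame(
    sample_id = sprintf("%s_%02d", ifelse(groups == "met", "M", "P"),
                        c(seq_len(config$n_primary), seq_len(config$n_met))),
    group = groups, stringsAsFactors = FALSE
  )
  mu <- cbind(primary = true_shift_track(config, "primary"),
              met = true_shift_track(config, "met"))
  cn <- mu[, groups, drop = FALSE] +
    matrix(stats::rnorm(n_snp * length(groups), sd = config$noise_sd_cn),
           nrow = n_snp)
  dimnames(cn) <- list(panel$probe_id, samples$sample_id)
  truth <- list(segment_map = config$segment_map, shift_tracks = mu,
                differential_snp = mu[, "primary"] != mu[, "met"])
  list(panel = panel, cn = cn, samples = samples, truth = truth)
}

#' Generate a synthetic expression cohort coupled to copy number
#'
#' Driver transcripts get expression baseline + \code{driver_beta} times the
#' mean true log2 copy number over their cis window; DE-only transcripts get
#' a pure group shift; the remainder are noise. Drivers are anchored at SNPs
#' inside group-differential segments; DE-only and null transcripts are
#' anchored so that their +/- \code{window_bp} window contains no
#' differential SNP, keeping the planted truth unambiguous.
#'
#' @param genomes result of [generate_genomes()].
#' @param config the same [sim_config()].
#' @return list with \code{expr} (matrix, transcripts x samples),
#'   \code{annotation} (data.frame: transcript_id, gene, chrom, start, end)
#'   and \code{truth} (list: driver_ids, de_only_ids, null_ids).
#' @export
generate_expression <- function(genomes, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config$seed, "expression"))
  panel <- genomes$panel
  n_snp <- nrow(panel)
  diff_snp <- genomes$truth$differential_snp
  half_gene <- 5000L  # 10 kb gene bodies centered on the anchor SNP

  # candidate anchors: drivers inside differential segments, others whose
  # window stays clear of any differential SNP
  driver_pool <- which(diff_snp)
  if (config$n_drivers > length(driver_pool))
    stop("n_drivers exceeds SNPs available in group-differential segments")
  clear <- vapply(seq_len(n_snp), function(i) {
    same <- panel$chrom == panel$chrom[i]
    near <- same & abs(panel$pos - panel$pos[i]) <= config$window_bp + half_gene
    !any(diff_snp[near])
  }, logical(1L))
  null_pool <- which(clear)
  n_other <- config$n_transcripts - config$n_drivers
  if (n_other > 0L && length(null_pool) == 0L)
    stop("no SNPs available outside differential windows")

  pick_spread <- function(pool, k) pool[unique(round(seq(1, length(pool),
                                                         length.out = k)))]
  driver_anchor <- if (config$n_drivers > 0L)
    sort(sample(driver_pool, config$n_drivers)) else integer()
  other_anchor <- sample(null_pool, n_other, replace = length(null_pool) < n_other)
  anchors <- c(driver_anchor, other_anchor)

  ids <- sprintf("t%04d", seq_len(config$n_transcripts))
  kind <- c(rep("driver", config$n_drivers),
            rep("de_only", config$n_de_only),
            rep("null", config$n_transcripts - config$n_drivers - config$n_de_only))
  annotation <- data.frame(
    transcript_id = ids,
    gene = sprintf("G%04d", seq_len(config$n_transcripts)),
    chrom = panel$chrom[anchors],
    start = pmax(1L, panel$pos[anchors] - half_gene),
    end = panel$pos[anchors] + half_gene,
    stringsAsFactors = FALSE
  )

  groups <- genomes$samples$group
  n_samp <- length(groups)
  mu_tracks <- genomes$truth$shift_tracks

  # mean true log2 CN over each transcript's window, per group
  window_cn <- function(anchor, group) {
    same <- panel$chrom == panel$chrom[anchor]
    w <- same & panel$pos >= annotation$start[match(anchor, anchors)] - config$window_bp &
      panel$pos <= annotation$end[match(anchor, anchors)] + config$window_bp
    mean(mu_tracks[w, group])
  }

  baseline <- stats::rnorm(config$n_transcripts, config$baseline_expr_mean,
                           config$baseline_expr_sd)
  expr <- matrix(stats::rnorm(config$n_transcripts * n_samp,
                              sd = config$noise_sd_expr),
                 nrow = config$n_transcripts)
  expr <- expr + baseline
  is_met <- groups == "met"
  for (j in seq_len(config$n_transcripts)) {
    if (kind[j] == "driver") {
      cn_p <- window_cn(anchors[j], "primary")
      cn_m <- window_cn(anchors[j], "met")
      expr[j, ] <- expr[j, ] + config$driver_beta * ifelse(is_met, cn_m, cn_p)
    } else if (kind[j] == "de_only") {
      expr[j, is_met] <- expr[j, is_met] + config$de_nondriver_effect
    }
  }
  dimnames(expr) <- list(ids, genomes$samples$sample_id)
  truth <- list(driver_ids = ids[kind == "driver"],
                de_only_ids = ids[kind == "de_only"],
                null_ids = ids[kind == "null"])
  list(expr = expr, annotation = annotation, truth = truth)
}

#' Generate a synthetic survival table with competing causes
#'
#' Each patient's latent disease-death, other-death and censoring times are
#' independent exponentials with cluster-specific cause hazards; the observed
#' record is the earliest, with status 0 (censored), 1 (disease death) or
#' 2 (other death). Covariates (age, sex, HPV status, AJCC stage) are drawn
#' independently of cluster so the cluster hazard ratio is interpretable in
#' recovery experiments.
#'
#' @param clusters integer vector of true cluster labels (1 or 2).
#' @param config a [sim_config()].
#' @return data.frame: patient_id, age, sex, hpv, stage, cluster, time,
#'   status.
#' @export
generate_survival <- function(clusters, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(clusters %in% c(1L, 2L))) stop("clusters must be 1 or 2")
  set.seed(stream_seed(config$seed, "survival"))
  n <- length(clusters)
  t_dis <- stats::rexp(n, config$hazard_disease[clusters])
  t_oth <- stats::rexp(n, config$hazard_other[clusters])
  t_cen <- if (config$hazard_censor > 0)
    stats::rexp(n, config$hazard_censor) else rep(Inf, n)
  time <- pmin(t_dis, t_oth, t_cen)
  status <- ifelse(time == t_dis, 1L, ifelse(time == t_oth, 2L, 0L))
  data.frame(
    patient_id = sprintf("pt_%03d", seq_len(n)),
    age = round(stats::rnorm(n, 60, 10), 1),
    sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.65, 0.35)),
    hpv = sample(c("high_risk", "negative"), n, replace = TRUE,
                 prob = c(0.35, 0.65)),
    stage = sample(c("I_II", "III_IV"), n, replace = TRUE),
    cluster = as.integer(clusters),
    time = time,
    status = status,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic siRNA viability screen
#'
#' Planted hit genes have true relative viability \code{hit_viability} in one
#' cell line (\code{nonhit_viability} elsewhere); replicate luminescence
#' readings are true viability times a line-specific plate scale times
#' multiplicative lognormal noise at the configured CV. Control wells
#' (transfection reagent only, gene \code{"CONTROL"}) have true viability 1.
#'
#' @param config a [sim_config()].
#' @return list with \code{screen} (data.frame: gene, cell_line, replicate,
#'   reading, is_control, set) and \code{truth} (list: hit genes per set and
#'   the true viability map).
#' @export
generate_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config$seed, "screen"))
  lines <- sprintf("line%d", seq_len(config$n_lines))
  sdlog <- sqrt(log(1 + config$replicate_cv^2))

  if (!is.null(config$suppression_effects)) {
    vmap <- config$suppression_effects
    colnames(vmap) <- lines
    set <- rep("custom", nrow(vmap))
    truth_hits <- list(signature_hits = NULL, background_hits = NULL)
  } else {
    genes_sig <- sprintf("SIG%03d", seq_len(config$n_signature_genes))
    genes_bg <- sprintf("KIN%03d", seq_len(config$n_background_genes))
    plant <- function(genes, n_hits) {
      v <- matrix(config$nonhit_viability, nrow = length(genes),
                  ncol = config$n_lines, dimnames = list(genes, lines))
      hit_genes <- if (n_hits > 0) sample(genes, n_hits) else character()
      for (g in hit_genes) v[g, sample(config$n_lines, 1L)] <- config$hit_viability
      list(v = v, hits = sort(hit_genes))
    }
    sig <- plant(genes_sig, config$n_hits_signature)
    bg <- plant(genes_bg, config$n_hits_background)
    vmap <- rbind(sig$v, bg$v)
    set <- c(rep("signature", config$n_signature_genes),
             rep("background", config$n_background_genes))
    truth_hits <- list(signature_hits = sig$hits, background_hits = bg$hits)
  }

  plate_scale <- stats::setNames(stats::runif(config$n_lines, 800, 1200), lines)
  rows <- expand.grid(gene = c(rownames(vmap), "CONTROL"),
                      cell_line = lines,
                      replicate = seq_len(config$n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- rows[order(rows$cell_line, rows$gene, rows$replicate), ]
  true_v <- rep(1, nrow(rows))
  gene_rows <- rows$gene != "CONTROL"
  true_v[gene_rows] <- vmap[cbind(rows$gene[gene_rows],
                                  rows$cell_line[gene_rows])]
  noise <- if (sdlog > 0)
    stats::rlnorm(nrow(rows), -sdlog^2 / 2, sdlog) else rep(1, nrow(rows))
  rows$reading <- true_v * plate_scale[rows$cell_line] * noise
  rows$is_control <- rows$gene == "CONTROL"
  rows$set <- c(set, "control")[match(rows$gene, c(rownames(vmap), "CONTROL"))]
  rownames(rows) <- NULL
  list(screen = rows,
       truth = c(truth_hits, list(viability_map = vmap)))
}
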