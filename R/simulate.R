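# Synthetic-data generator: emits annotation geometry, expression matrices,
# interaction tables and survival records with known ground truth, emulating
# the study's inputs (19 tumor / 9 control microarray cohort; TCGA-style
# RNA-Seq cohort for sponge and survival stages). Every planted structure is
# recorded so recovery is checkable stage by stage.
#
# RNG discipline: each file class draws from its own stream, seeded as
# seed + fixed per-class offset, so regenerating one class never perturbs
# another.

.SEED_OFFSETS <- c(annotation = 101L, expression = 202L,
                   survival = 303L, interactions = 404L)

#' Simulate gene annotation with known positional ground truth
#'
#' Lays out protein-coding genes (2-10 exons each) without mutual overlap on
#' synthetic chromosomes, then places lncRNAs so that every positional
#' subtype is realized with a known label: partial exon overlaps (sense and
#' antisense), intron-contained lncRNAs (both strands), divergent
#' transcription partners within the 1 kb TSS window, and intergenic
#' lncRNAs. A subset of intergenic lncRNAs is placed 100-400 kb from an
#' anchor gene (inside the 500 kb cis window) as planted cis partners; the
#' rest sit ~700 kb away, outside it. Alternate exon-sense lncRNAs are fully
#' contained in an mRNA exon, giving known positives for the exon-overlap
#' removal rule. miRNA hairpins are embedded on the same strand inside host
#' lncRNA spans; remaining miRNAs land in gene-free territory.
#'
#' @param n_mrna,n_lnc,n_mirna Feature counts (n_mirna covers hosted plus
#'   free miRNAs; `n_host` of them are embedded in lncRNAs).
#' @param n_cis_pairs Number of intergenic lncRNAs planted as cis partners.
#' @param n_host Number of miRNAs embedded in host lncRNAs.
#' @param seed Integer seed.
#' @param chrom_length Optional chromosome length (bp); auto-sized when NULL,
#'   errors with a suggested size when too small.
#' @return List with `annotation` (a [gene_annotation()] covering all three
#'   biotypes) and `truth` (subtype labels, exon-contained ids, planted cis
#'   pairs, host pairs).
#' @export
simulate_annotation <- function(n_mrna = 300L, n_lnc = 300L, n_mirna = 60L,
                                n_cis_pairs = 10L, n_host = 8L, seed = 1L,
                                chrom_length = NULL) {
  stopifnot(n_mrna >= 6L, n_lnc >= 6L, n_mirna >= n_host,
            n_cis_pairs + 5L <= n_lnc, n_host <= n_lnc)
  set.seed(seed + .SEED_OFFSETS[["annotation"]])
  spacing <- 2e6
  chroms <- c("chr1", "chr2")
  per_chrom <- ceiling(n_mrna / 2)
  needed <- 1e6 + per_chrom * spacing + n_mirna * 1000 + 2e6
  if (!is.null(chrom_length) && chrom_length < needed)
    stop(sprintf("chromosome too small: need >= %.0f bp for this layout",
                 needed))

  # --- protein-coding genes ---
  mr <- vector("list", n_mrna)
  for (i in seq_len(n_mrna)) {
    chrom <- chroms[((i - 1L) %/% per_chrom) + 1L]
    slot <- (i - 1L) %% per_chrom
    gs <- as.integer(1e6 + slot * spacing)
    n_ex <- sample(2:10, 1L)
    ex_len <- sample(400:2000, n_ex, replace = TRUE)
    in_len <- if (n_ex > 1L) sample(5000:20000, n_ex - 1L, replace = TRUE)
              else integer(0)
    starts <- gs + cumsum(c(0L, ex_len[-n_ex] + in_len))
    ex <- cbind(start = as.integer(starts),
                end = as.integer(starts + ex_len))
    mr[[i]] <- list(id = sprintf("MRNA%04d", i), chrom = chrom,
                    start = gs, end = ex[n_ex, 2L],
                    strand = if (i %% 2L) "+" else "-", exons = ex)
  }

  # --- lncRNAs: one of each overlap subtype first, then an intergenic-heavy
  # remainder (intergenic dominates real dysregulated sets) ---
  others <- c("exon_sense_overlapping", "natural_antisense",
              "intron_sense_overlapping", "intronic_antisense",
              "bidirectional")
  n_intergenic <- max(n_cis_pairs, 1L,
                      min(n_lnc - 5L, ceiling(n_lnc * 0.4)))
  sub_alloc <- c(others,
                 rep("intergenic", n_intergenic),
                 rep(others, length.out = n_lnc - 5L - n_intergenic))

  lnc <- vector("list", n_lnc)
  truth_subtype <- character(n_lnc)
  exon_contained <- character(0)
  cis_pairs <- data.frame(lncrna_id = character(0), mrna_id = character(0),
                          stringsAsFactors = FALSE)
  n_cis_assigned <- 0L
  eso_seen <- 0L
  for (i in seq_len(n_lnc)) {
    g <- mr[[((i - 1L) %% n_mrna) + 1L]]
    id <- sprintf("LNC%04d", i)
    sub <- sub_alloc[i]
    anti <- if (g$strand == "+") "-" else "+"
    ex <- g$exons
    rec <- switch(sub,
      exon_sense_overlapping = {
        eso_seen <- eso_seen + 1L
        if (eso_seen %% 2L == 0L) {
          # fully contained in the widest exon -> removal-rule positive
          w <- which.max(ex[, 2L] - ex[, 1L])
          len <- min(ex[w, 2L] - ex[w, 1L] - 20L, 300L)
          exon_contained <- c(exon_contained, id)
          list(start = ex[w, 1L] + 10L, end = ex[w, 1L] + 10L + len,
               strand = g$strand)
        } else {
          list(start = ex[1L, 1L] - 400L, end = ex[1L, 1L] + 200L,
               strand = g$strand)
        }
      },
      natural_antisense = list(start = ex[1L, 1L] - 200L,
                               end = ex[1L, 1L] + 300L, strand = anti),
      intron_sense_overlapping = list(start = ex[1L, 2L] + 100L,
                                      end = min(ex[2L, 1L] - 100L,
                                                ex[1L, 2L] + 2100L),
                                      strand = g$strand),
      intronic_antisense = list(start = ex[1L, 2L] + 100L,
                                end = min(ex[2L, 1L] - 100L,
                                          ex[1L, 2L] + 2100L),
                                strand = anti),
      bidirectional = {
        d <- sample(200:900, 1L)
        if (g$strand == "+")
          list(start = g$start - d - 3000L, end = g$start - d, strand = "-")
        else
          list(start = g$end + d, end = g$end + d + 3000L, strand = "+")
      },
      intergenic = {
        span <- sample(5000:10000, 1L)
        off <- if (n_cis_assigned < n_cis_pairs) {
          n_cis_assigned <- n_cis_assigned + 1L
          cis_pairs <- rbind(cis_pairs,
                             data.frame(lncrna_id = id, mrna_id = g$id,
                                        stringsAsFactors = FALSE))
          sample(100000:400000, 1L)
        } else sample(700000:710000, 1L)
        list(start = g$end + off, end = g$end + off + span,
             strand = sample(c("+", "-"), 1L))
      })
    truth_subtype[i] <- sub
    lnc[[i]] <- list(id = id, chrom = g$chrom,
                     start = as.integer(rec$start), end = as.integer(rec$end),
                     strand = rec$strand)
  }
  names(truth_subtype) <- vapply(lnc, `[[`, "", "id")

  # --- miRNAs: hosted inside intergenic lncRNA spans, rest in dead zone ---
  host_cand <- which(truth_subtype == "intergenic")
  if (length(host_cand) < n_host)
    host_cand <- c(host_cand, which(truth_subtype == "intron_sense_overlapping"))
  if (length(host_cand) < n_host)
    stop("not enough intergenic/intronic lncRNAs to host ", n_host, " miRNAs")
  host_idx <- host_cand[seq_len(n_host)]
  dead_start <- as.integer(1e6 + per_chrom * spacing + 8e5)
  mir <- vector("list", n_mirna)
  host_pairs <- data.frame(lncrna_id = character(0), mirna_id = character(0),
                           stringsAsFactors = FALSE)
  for (i in seq_len(n_mirna)) {
    id <- sprintf("MIR%04d", i)
    if (i <= n_host) {
      h <- lnc[[host_idx[i]]]
      mir[[i]] <- list(id = id, chrom = h$chrom,
                       start = h$start + 50L, end = h$start + 130L,
                       strand = h$strand)
      host_pairs <- rbind(host_pairs,
                          data.frame(lncrna_id = h$id, mirna_id = id,
                                     stringsAsFactors = FALSE))
    } else {
      mir[[i]] <- list(id = id, chrom = "chr1",
                       start = dead_start + i * 1000L,
                       end = dead_start + i * 1000L + 80L,
                       strand = sample(c("+", "-"), 1L))
    }
  }

  all_rec <- c(mr, lnc, mir)
  ann <- gene_annotation(
    gene_id = vapply(all_rec, `[[`, "", "id"),
    chrom = vapply(all_rec, `[[`, "", "chrom"),
    start = vapply(all_rec, function(r) r$start, 0L),
    end = vapply(all_rec, function(r) r$end, 0L),
    strand = vapply(all_rec, `[[`, "", "strand"),
    biotype = c(rep("mRNA", n_mrna), rep("lncRNA", n_lnc),
                rep("miRNA", n_mirna)),
    exons = c(lapply(mr, `[[`, "exons"),
              lapply(lnc, function(r) cbind(start = r$start, end = r$end)),
              lapply(mir, function(r) cbind(start = r$start, end = r$end))))
  list(annotation = ann,
       truth = list(subtype_of = truth_subtype,
                    exon_contained = exon_contained,
                    planted_cis_pairs = cis_pairs,
                    host_pairs = host_pairs))
}

#' Simulate expression matrices with planted structure
#'
#' Log2-scale Gaussian intensities (unit noise) for lncRNA, mRNA and miRNA
#' feature classes over tumor and control samples. Planted structure:
#' differentially expressed features are shifted by `effect_log2fc` in tumor
#' samples; each planted cis pair shares a latent factor giving correlation
#' `rho_cis` between its members; each sponge chain follows
#' `miRNA = a - beta * lncRNA_deviation + noise` and
#' `mRNA = b - beta * miRNA_deviation + noise` in tumor samples (noise sd
#' `sqrt(1 - beta^2)`, so the arm correlations are -beta), with all three
#' members upregulated and the lncRNA baseline 2 log2 units above its mRNA.
#' All other features are independent.
#'
#' @param sim Output of [simulate_annotation()].
#' @param n_tumor,n_control Sample counts (>= 4 and >= 2).
#' @param effect_log2fc Planted log2 fold change of DE features.
#' @param rho_cis Latent-factor correlation of planted cis pairs.
#' @param beta_sponge Chain coefficient of planted sponge triplets.
#' @param n_sponge Number of planted sponge triplets.
#' @param n_decoy Number of decoy triplets wired into the interaction tables
#'   without planted correlation structure.
#' @param de_fraction Fraction of each feature class made DE (beyond the
#'   planted members).
#' @param host_concordant_fraction Fraction of hosted miRNAs regulated in the
#'   same direction as their host lncRNA.
#' @param with_flags Attach Present/Absent detection flags to the lncRNA and
#'   mRNA matrices (a 5% tranche of non-planted features is Absent
#'   everywhere, exercising the flag filter).
#' @param seed Integer seed.
#' @return List with `lnc_expr`, `mrna_expr`, `mir_expr`
#'   ([expression_matrix()] objects), `predicted` / `validated`
#'   ([interaction_table()] objects wiring planted and decoy chains), and
#'   `truth` (the input truth extended with `de`, `sponge_triplets`,
#'   `decoy_triplets`, `host_concordant`).
#' @export
simulate_expression <- function(sim, n_tumor = 19L, n_control = 9L,
                                effect_log2fc = 2, rho_cis = 0.9,
                                beta_sponge = 0.8, n_sponge = 10L,
                                n_decoy = 50L, de_fraction = 0.25,
                                host_concordant_fraction = 0.7,
                                with_flags = TRUE, seed = 1L) {
  stopifnot(n_tumor >= 4L, n_control >= 2L)
  if (rho_cis < 0 || rho_cis > 1) stop("rho_cis must lie in [0, 1]")
  if (beta_sponge <= 0 || beta_sponge >= 1)
    stop("beta_sponge must lie in (0, 1)")
  if (effect_log2fc < 0) stop("effect_log2fc must be >= 0")
  set.seed(seed + .SEED_OFFSETS[["expression"]])
  ann <- sim$annotation
  truth <- sim$truth
  lnc_ids <- ann$gene_id[ann$biotype == "lncRNA"]
  mrna_ids <- ann$gene_id[ann$biotype == "mRNA"]
  mir_ids <- ann$gene_id[ann$biotype == "miRNA"]
  samples <- c(sprintf("GBM%03d", seq_len(n_tumor)),
               sprintf("CTRL%03d", seq_len(n_control)))
  groups <- stats::setNames(rep(c("tumor", "control"), c(n_tumor, n_control)),
                            samples)
  is_tumor <- groups == "tumor"

  # planted roles
  cis <- truth$planted_cis_pairs
  host <- truth$host_pairs
  free_lnc <- setdiff(lnc_ids, c(cis$lncrna_id, host$lncrna_id))
  if (length(free_lnc) < n_sponge)
    stop("not enough unassigned lncRNAs for n_sponge; raise n_lnc")
  sponge_lnc <- sample(free_lnc, n_sponge)
  free_mir <- setdiff(mir_ids, host$mirna_id)
  if (length(free_mir) < n_sponge + n_decoy)
    stop("need n_mirna >= n_host + n_sponge + n_decoy")
  sponge_mir <- sample(free_mir, n_sponge)
  decoy_mir <- sample(setdiff(free_mir, sponge_mir), n_decoy)
  free_mrna <- setdiff(mrna_ids, cis$mrna_id)
  if (length(free_mrna) < n_sponge)
    stop("not enough mRNAs free of cis planting for n_sponge")
  sponge_mrna <- sample(free_mrna, n_sponge)
  sponge <- data.frame(lncrna_id = sponge_lnc, mirna_id = sponge_mir,
                       mrna_id = sponge_mrna, stringsAsFactors = FALSE)
  decoy <- data.frame(
    lncrna_id = sample(setdiff(lnc_ids, sponge_lnc), n_decoy, replace = TRUE),
    mirna_id = decoy_mir,
    mrna_id = sample(setdiff(mrna_ids, sponge_mrna), n_decoy, replace = TRUE),
    stringsAsFactors = FALSE)

  # DE direction per feature class
  cis_dir <- sample(c("up", "down"), nrow(cis), replace = TRUE)
  host_dir <- sample(c("up", "down"), nrow(host), replace = TRUE)
  concordant <- seq_len(nrow(host)) <=
    round(host_concordant_fraction * nrow(host))
  mir_host_dir <- ifelse(concordant, host_dir,
                         ifelse(host_dir == "up", "down", "up"))

  assign_de <- function(ids, forced_up, forced_down) {
    dir <- stats::setNames(rep("unchanged", length(ids)), ids)
    dir[forced_up] <- "up"; dir[forced_down] <- "down"
    n_extra <- max(0L, round(de_fraction * length(ids)) -
                     sum(dir != "unchanged"))
    pool <- names(dir)[dir == "unchanged"]
    extra <- sample(pool, min(n_extra, length(pool)))
    half <- length(extra) %/% 2L
    dir[extra[seq_len(half)]] <- "up"
    dir[setdiff(extra, extra[seq_len(half)])] <- "down"
    dir
  }
  lnc_dir <- assign_de(lnc_ids,
                       forced_up = c(sponge_lnc, cis$lncrna_id[cis_dir == "up"],
                                     host$lncrna_id[host_dir == "up"]),
                       forced_down = c(cis$lncrna_id[cis_dir == "down"],
                                       host$lncrna_id[host_dir == "down"]))
  mrna_dir <- assign_de(mrna_ids,
                        forced_up = c(sponge_mrna,
                                      cis$mrna_id[cis_dir == "up"]),
                        forced_down = cis$mrna_id[cis_dir == "down"])
  mir_dir <- assign_de(mir_ids,
                       forced_up = c(sponge_mir,
                                     host$mirna_id[mir_host_dir == "up"]),
                       forced_down = host$mirna_id[mir_host_dir == "down"])

  n_s <- length(samples)
  gen_class <- function(ids, mu0, dir) {
    # between-gene baseline spread of 2 log2 units (typical intensity range);
    # keeps planted tail features rank-resolvable under quantile normalization
    mu <- stats::rnorm(length(ids), mu0, 2)
    delta <- ifelse(dir[ids] == "up", effect_log2fc,
                    ifelse(dir[ids] == "down", -effect_log2fc, 0))
    v <- matrix(stats::rnorm(length(ids) * n_s), length(ids), n_s,
                dimnames = list(ids, samples))
    v + mu + outer(delta, as.numeric(is_tumor))
  }
  lnc_v <- gen_class(lnc_ids, 7, lnc_dir)
  mrna_v <- gen_class(mrna_ids, 8, mrna_dir)
  mir_v <- gen_class(mir_ids, 6, mir_dir)

  # planted cis pairs: shared latent factor across all samples
  for (k in seq_len(nrow(cis))) {
    f <- stats::rnorm(n_s)
    a <- sqrt(rho_cis); b <- sqrt(1 - rho_cis)
    l <- cis$lncrna_id[k]; m <- cis$mrna_id[k]
    base_l <- mean(lnc_v[l, is_tumor]) ; base_lc <- mean(lnc_v[l, !is_tumor])
    base_m <- mean(mrna_v[m, is_tumor]); base_mc <- mean(mrna_v[m, !is_tumor])
    mu_l <- ifelse(is_tumor, base_l, base_lc)
    mu_m <- ifelse(is_tumor, base_m, base_mc)
    lnc_v[l, ] <- mu_l + a * f + b * stats::rnorm(n_s)
    mrna_v[m, ] <- mu_m + a * f + b * stats::rnorm(n_s)
  }

  # planted sponge chains in tumor samples; baseline offset lnc = mrna + 2
  sd_e <- sqrt(1 - beta_sponge^2)
  for (k in seq_len(n_sponge)) {
    l <- sponge$lncrna_id[k]; mi <- sponge$mirna_id[k]; r <- sponge$mrna_id[k]
    # modest-abundance target mRNA; sponge lncRNA 2 log2 units above it, so
    # neither feature saturates the rank scale under quantile normalization
    mu0_r <- stats::rnorm(1, 6.5, 0.5)
    mu_r <- mu0_r + effect_log2fc          # tumor-side mRNA mean
    mu_l <- mu_r + 2
    mu_mi <- mean(mir_v[mi, is_tumor])
    u <- stats::rnorm(n_tumor)
    v_mi <- -beta_sponge * u + sd_e * stats::rnorm(n_tumor)
    v_r <- -beta_sponge * v_mi + sd_e * stats::rnorm(n_tumor)
    lnc_v[l, is_tumor] <- mu_l + u
    mir_v[mi, is_tumor] <- mu_mi + v_mi
    mrna_v[r, is_tumor] <- mu_r + v_r
    mrna_v[r, !is_tumor] <- mu0_r + stats::rnorm(n_control)
    lnc_v[l, !is_tumor] <- mu_l - effect_log2fc + stats::rnorm(n_control)
  }

  # detection flags: a tranche of non-planted features Absent everywhere
  mk_flags <- function(ids, v) {
    fl <- matrix("P", nrow(v), ncol(v), dimnames = dimnames(v))
    fl[sample(length(fl), round(0.02 * length(fl)))] <- "M"
    planted <- c(cis$lncrna_id, cis$mrna_id, host$lncrna_id,
                 sponge$lncrna_id, sponge$mrna_id)
    pool <- setdiff(ids, planted)
    absent <- sample(pool, min(length(pool), round(0.05 * length(ids))))
    fl[absent, ] <- "A"
    fl
  }
  lnc_flags <- if (with_flags) mk_flags(lnc_ids, lnc_v) else NULL
  mrna_flags <- if (with_flags) mk_flags(mrna_ids, mrna_v) else NULL

  predicted <- interaction_table(
    c(sponge$lncrna_id, decoy$lncrna_id),
    c(sponge$mirna_id, decoy$mirna_id),
    evidence = "predicted", origin = "synthetic-mircode-like")
  validated <- interaction_table(
    c(sponge$mirna_id, decoy$mirna_id),
    c(sponge$mrna_id, decoy$mrna_id),
    evidence = "validated", origin = "synthetic-mirwalk-like")

  truth$de <- list(
    lnc = list(up = names(lnc_dir)[lnc_dir == "up"],
               down = names(lnc_dir)[lnc_dir == "down"]),
    mrna = list(up = names(mrna_dir)[mrna_dir == "up"],
                down = names(mrna_dir)[mrna_dir == "down"]),
    mir = list(up = names(mir_dir)[mir_dir == "up"],
               down = names(mir_dir)[mir_dir == "down"]))
  truth$sponge_triplets <- sponge
  truth$decoy_triplets <- decoy
  truth$host_concordant <- stats::setNames(concordant, host$lncrna_id)

  list(lnc_expr = expression_matrix(lnc_v, groups, "log2", lnc_flags),
       mrna_expr = expression_matrix(mrna_v, groups, "log2", mrna_flags),
       mir_expr = expression_matrix(mir_v, groups, "log2"),
       predicted = predicted, validated = validated, truth = truth)
}

#' Simulate proportional-hazards survival records
#'
#' Event times are exponential with rate `lambda0 * exp(lp)` where `lp` is
#' the sum of planted coefficients times centred log2 expression of the
#' signature features; `lambda0` puts the baseline median at 15 months.
#' Censoring is independent uniform on (0, b) with b calibrated so the
#' expected censored fraction equals `censor_frac`. Covariates (age in years,
#' binary G-CIMP / IDH1 / MGMT markers) are generated independent of the
#' score.
#'
#' @param lnc_expr An [expression_matrix()] whose tumor samples form the
#'   cohort.
#' @param signature Named numeric vector: planted coefficient per feature
#'   (log-hazard per log2 unit).
#' @param censor_frac Target censored fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return List with `surv` (a [survival_table()] over the tumor samples) and
#'   `truth_signature` (the planted coefficients).
#' @export
simulate_survival <- function(lnc_expr, signature, censor_frac = 0.3,
                              seed = 1L) {
  stopifnot(inherits(lnc_expr, "expression_matrix"),
            censor_frac >= 0, censor_frac < 1,
            all(is.finite(signature)), length(signature) >= 1L)
  missing <- setdiff(names(signature), rownames(lnc_expr$values))
  if (length(missing))
    stop("signature feature(s) not in matrix: ", paste(missing, collapse = ", "))
  set.seed(seed + .SEED_OFFSETS[["survival"]])
  samp <- names(lnc_expr$groups)[lnc_expr$groups == "tumor"]
  x <- lnc_expr$values[names(signature), samp, drop = FALSE]
  xc <- x - rowMeans(x)
  lp <- as.numeric(crossprod(xc, signature))
  lambda0 <- log(2) / 15
  t_event <- stats::rexp(length(samp), rate = lambda0 * exp(lp))
  if (censor_frac == 0) {
    time <- t_event; event <- rep(1L, length(samp))
  } else {
    f <- function(b) mean(pmin(t_event / b, 1)) - censor_frac
    b <- stats::uniroot(f, c(min(t_event) / 100, max(t_event) * 100))$root
    cens <- stats::runif(length(samp), 0, b)
    event <- as.integer(t_event <= cens)
    time <- pmin(t_event, cens)
  }
  cov <- data.frame(age = round(stats::rnorm(length(samp), 58, 10)),
                    g_cimp = stats::rbinom(length(samp), 1L, 0.1),
                    idh1 = stats::rbinom(length(samp), 1L, 0.08),
                    mgmt = stats::rbinom(length(samp), 1L, 0.45))
  list(surv = survival_table(samp, time, event, covariates = cov),
       truth_signature = signature)
}

#' Simulate a complete glioblastoma-style dataset
#'
#' One call wiring [simulate_annotation()], [simulate_expression()] and
#' [simulate_survival()] into the full input set the pipeline consumes, with
#' the combined ground truth attached. The default preset mirrors the study's
#' microarray cohort (19 tumors, 9 controls); raise `n_tumor` for TCGA-style
#' stages (sponge inference, survival).
#'
#' @inheritParams simulate_annotation
#' @inheritParams simulate_expression
#' @param n_signature Number of lncRNAs given nonzero survival coefficients
#'   (alternating +0.5 / -0.5, drawn from planted-structure-free intergenic
#'   lncRNAs where possible).
#' @param censor_frac Target censored fraction.
#' @param seed Integer seed; all per-class streams derive from it.
#' @return List with `annotation`, `lnc_expr`, `mrna_expr`, `mir_expr`,
#'   `predicted`, `validated`, `surv`, and `truth`.
#' @export
simulate_gbm_dataset <- function(n_mrna = 300L, n_lnc = 300L,
                                 n_cis_pairs = 10L, n_host = 8L,
                                 n_sponge = 10L, n_decoy = 50L,
                                 n_tumor = 19L, n_control = 9L,
                                 effect_log2fc = 2, rho_cis = 0.9,
                                 beta_sponge = 0.8, de_fraction = 0.25,
                                 host_concordant_fraction = 0.7,
                                 n_signature = 5L, censor_frac = 0.3,
                                 with_flags = TRUE, seed = 1L) {
  n_mirna <- n_host + n_sponge + n_decoy + 5L
  sim <- simulate_annotation(n_mrna, n_lnc, n_mirna,
                             n_cis_pairs = n_cis_pairs, n_host = n_host,
                             seed = seed)
  ex <- simulate_expression(sim, n_tumor = n_tumor, n_control = n_control,
                            effect_log2fc = effect_log2fc, rho_cis = rho_cis,
                            beta_sponge = beta_sponge, n_sponge = n_sponge,
                            n_decoy = n_decoy, de_fraction = de_fraction,
                            host_concordant_fraction = host_concordant_fraction,
                            with_flags = with_flags, seed = seed)
  truth <- ex$truth
  planted <- unique(c(truth$planted_cis_pairs$lncrna_id,
                      truth$host_pairs$lncrna_id,
                      truth$sponge_triplets$lncrna_id))
  intergenic <- names(truth$subtype_of)[truth$subtype_of == "intergenic"]
  pool <- setdiff(intergenic, planted)
  if (length(pool) < n_signature)
    pool <- c(pool, setdiff(intergenic, pool))
  sig_feats <- utils::head(pool, n_signature)
  signature <- stats::setNames(
    rep(c(0.5, -0.5), length.out = length(sig_feats)), sig_feats)
  sv <- simulate_survival(ex$lnc_expr, signature,
                          censor_frac = censor_frac, seed = seed)
  truth$survival_signature <- sv$truth_signature
  list(annotation = sim$annotation,
       lnc_expr = ex$lnc_expr, mrna_expr = ex$mrna_expr,
       mir_expr = ex$mir_expr,
       predicted = ex$predicted, validated = ex$validated,
       surv = sv$surv, truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Emits every input file the pipeline reads: annotation as GTF (plus the
#' miRNA subset as BED6), the three expression matrices with one shared
#' sample sheet, the predicted and validated interaction tables, the survival
#' table, and the ground truth as JSON.
#'
#' @param dataset Output of [simulate_gbm_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_annotation_gtf(dataset$annotation, p("annotation.gtf"))
  mir_ann <- dataset$annotation[dataset$annotation$biotype == "miRNA", ]
  write_annotation_bed6(mir_ann, p("mirna.bed"))
  write_expression(dataset$lnc_expr, p("lnc_expr.tsv"), p("samples.tsv"))
  write_expression(dataset$mrna_expr, p("mrna_expr.tsv"))
  write_expression(dataset$mir_expr, p("mir_expr.tsv"))
  write_interactions(dataset$predicted, p("predicted.tsv"))
  write_interactions(dataset$validated, p("validated.tsv"))
  write_survival(dataset$surv, p("survival.tsv"))
  tr <- dataset$truth
  jsonlite::write_json(tr, p("truth.json"), auto_unbox = TRUE, digits = NA)
  files <- c(annotation = p("annotation.gtf"), mirna_bed = p("mirna.bed"),
             lnc_expr = p("lnc_expr.tsv"), mrna_expr = p("mrna_expr.tsv"),
             mir_expr = p("mir_expr.tsv"), samples = p("samples.tsv"),
             predicted = p("predicted.tsv"), validated = p("validated.tsv"),
             survival = p("survival.tsv"), truth = p("truth.json"))
  invisible(files)
}
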