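# Synthetic two-class expression cohorts with a planted lncRNA/mRNA pair.
#
# The generator emulates a responder/nonresponder drug-response cohort
# profiled on a log2-intensity scale: one lncRNA shifted up and one mRNA
# shifted down in responders, the two correlated within each class, on a
# background of independent genes of which a small fraction carries
# unrelated class effects. Companion generators emit a STRING-like weighted
# interaction network in which the planted genes are hubs, a drug-target
# list containing the planted mRNA among decoys, and qPCR tables normalized
# to a housekeeping reference.

#' Simulation configuration
#'
#' Builds and validates the parameter set shared by all generators.
#'
#' @param n_responders,n_nonresponders samples per class (each >= 2).
#' @param n_lnc_background,n_mrna_background background genes per matrix
#'   (the signal pair and two housekeeping references are added on top).
#' @param effect_size_d mean log2 shift of the signal genes between classes:
#'   the signal lncRNA is `+d` and the signal mRNA `-d` in responders.
#' @param within_class_rho Pearson correlation of the signal pair within
#'   each class (`|rho| < 1`).
#' @param noise_sd residual within-class standard deviation, log2 units.
#' @param bg_de_fraction fraction of background genes given a random class
#'   effect (magnitude uniform on `bg_effect_range`, random sign).
#' @param bg_effect_range length-2 numeric, magnitude range of background
#'   class effects (log2 units).
#' @param n_network_nodes,network_attachment size and preferential-attachment
#'   parameter (edges added per new node) of the interaction network.
#' @param n_decoy_targets decoy mRNAs on the drug-target list; the default
#'   yields a 57-gene list (1 signal + 56 decoys).
#' @param seed integer seed; every generator derives its stream from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_responders = 20L, n_nonresponders = 20L,
                       n_lnc_background = 100L, n_mrna_background = 150L,
                       effect_size_d = 1.5, within_class_rho = 0.8,
                       noise_sd = 0.7, bg_de_fraction = 0.1,
                       bg_effect_range = c(0.8, 2),
                       n_network_nodes = 60L, network_attachment = 2L,
                       n_decoy_targets = 56L, seed = 1L) {
  cfg <- list(n_responders = as.integer(n_responders),
              n_nonresponders = as.integer(n_nonresponders),
              n_lnc_background = as.integer(n_lnc_background),
              n_mrna_background = as.integer(n_mrna_background),
              effect_size_d = effect_size_d,
              within_class_rho = within_class_rho,
              noise_sd = noise_sd,
              bg_de_fraction = bg_de_fraction,
              bg_effect_range = bg_effect_range,
              n_network_nodes = as.integer(n_network_nodes),
              network_attachment = as.integer(network_attachment),
              n_decoy_targets = as.integer(n_decoy_targets),
              seed = as.integer(seed))
  if (cfg$n_responders < 2L || cfg$n_nonresponders < 2L)
    stop("invalid config: need at least 2 samples per class", call. = FALSE)
  if (cfg$n_lnc_background < 1L || cfg$n_mrna_background < 1L)
    stop("invalid config: background gene counts must be positive", call. = FALSE)
  if (!is.finite(cfg$within_class_rho) || abs(cfg$within_class_rho) >= 1)
    stop("invalid config: |within_class_rho| must be < 1", call. = FALSE)
  if (!is.finite(cfg$noise_sd) || cfg$noise_sd <= 0)
    stop("invalid config: noise_sd must be positive", call. = FALSE)
  if (cfg$bg_de_fraction < 0 || cfg$bg_de_fraction > 1)
    stop("invalid config: bg_de_fraction must lie in [0, 1]", call. = FALSE)
  if (cfg$n_network_nodes < 2L)
    stop("invalid config: n_network_nodes must be at least 2", call. = FALSE)
  if (cfg$n_decoy_targets < 0L)
    stop("invalid config: n_decoy_targets must be non-negative", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Housekeeping reference gene ids carried by every simulated cohort
#' @keywords internal
REFERENCE_GENES <- c("RN18S", "GAPDH")

#' Generate a two-class expression cohort with a planted signal pair
#'
#' Draws log2-scale expression for lncRNAs and mRNAs in a responder /
#' nonresponder cohort. The planted lncRNA has mean shift `+d` and the
#' planted mRNA `-d` in responders; within each class the pair follows a
#' bivariate normal with correlation `within_class_rho`. Background genes
#' are independent Gaussians around gene-specific baselines, a fraction of
#' them with random class effects. The mRNA matrix additionally carries the
#' housekeeping references `RN18S` and `GAPDH` (no class effect, sd 0.1)
#' used by [generate_qpcr()].
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_cohort`: `expr_lnc` and `expr_mrna`
#'   (genes x samples matrices), `labels` (data.frame `sample_id`,
#'   `response`), `truth` (planted-pair record) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n1 <- config$n_responders; n2 <- config$n_nonresponders
  n <- n1 + n2
  sample_id <- sprintf("S%03d", seq_len(n))
  response <- c(rep("responder", n1), rep("nonresponder", n2))
  labels <- data.frame(sample_id = sample_id, response = response,
                       stringsAsFactors = FALSE)

  lnc_ids <- sprintf("LNC%04d", seq_len(config$n_lnc_background + 1L))
  mrna_ids <- sprintf("MRNA%04d", seq_len(config$n_mrna_background + 1L))
  signal_lnc <- lnc_ids[length(lnc_ids)]
  signal_mrna <- mrna_ids[length(mrna_ids)]

  d <- config$effect_size_d
  rho <- config$within_class_rho
  sdv <- config$noise_sd

  # signal pair: bivariate normal within each class, via Cholesky
  draw_pair <- function(m, mu_lnc, mu_mrna) {
    z1 <- stats::rnorm(m); z2 <- stats::rnorm(m)
    lnc <- mu_lnc + sdv * z1
    mrna <- mu_mrna + sdv * (rho * z1 + sqrt(1 - rho^2) * z2)
    cbind(lnc, mrna)
  }
  base_lnc <- 6; base_mrna <- 8
  resp <- draw_pair(n1, base_lnc + d, base_mrna - d)
  nonr <- draw_pair(n2, base_lnc, base_mrna)
  sig_lnc_expr <- c(resp[, 1], nonr[, 1])
  sig_mrna_expr <- c(resp[, 2], nonr[, 2])

  bg_matrix <- function(ids) {
    g <- length(ids)
    baseline <- stats::runif(g, 4, 12)
    is_de <- stats::runif(g) < config$bg_de_fraction
    eff <- ifelse(is_de,
                  sample(c(-1, 1), g, replace = TRUE) *
                    stats::runif(g, config$bg_effect_range[1],
                                 config$bg_effect_range[2]),
                  0)
    m <- matrix(stats::rnorm(g * n, sd = sdv), nrow = g)
    m <- m + baseline
    m[, seq_len(n1)] <- m[, seq_len(n1)] + eff
    rownames(m) <- ids
    colnames(m) <- sample_id
    list(m = m, effects = eff)
  }

  bg_l <- bg_matrix(lnc_ids[-length(lnc_ids)])
  bg_m <- bg_matrix(mrna_ids[-length(mrna_ids)])

  expr_lnc <- rbind(bg_l$m, matrix(sig_lnc_expr, nrow = 1,
                                   dimnames = list(signal_lnc, sample_id)))
  # housekeeping references: high, tight, no class effect
  ref <- matrix(stats::rnorm(2L * n, mean = c(13, 11), sd = 0.1), nrow = 2,
                dimnames = list(REFERENCE_GENES, sample_id))
  expr_mrna <- rbind(bg_m$m,
                     matrix(sig_mrna_expr, nrow = 1,
                            dimnames = list(signal_mrna, sample_id)),
                     ref)

  truth <- list(signal_lnc_id = signal_lnc,
                signal_mrna_id = signal_mrna,
                effect_lnc = +d, effect_mrna = -d,
                within_class_rho = rho,
                lnc_background_ids = lnc_ids[-length(lnc_ids)],
                mrna_background_ids = mrna_ids[-length(mrna_ids)],
                bg_effects_lnc = bg_l$effects,
                bg_effects_mrna = bg_m$effects)

  structure(list(expr_lnc = expr_lnc, expr_mrna = expr_mrna,
                 labels = labels, truth = truth, config = config),
            class = "sim_cohort")
}

#' Generate a STRING-like weighted interaction network with planted hubs
#'
#' Grows an undirected preferential-attachment graph over a subset of the
#' cohort's gene ids and assigns the two planted genes to the two
#' highest-degree vertices, guaranteeing they are hubs; an edge between
#' them is added if attachment did not create one. Each edge carries an
#' integer combined score drawn uniformly from 1..1000.
#'
#' @param truth the `truth` record of a [generate_cohort()] result.
#' @param config the matching [sim_config()].
#' @return data.frame with columns `node1`, `node2`, `combined_score`.
#' @export
generate_network <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_network_nodes
  if (n < 2L) stop("invalid config: need at least 2 network nodes", call. = FALSE)
  set.seed(config$seed + 1L)

  g <- igraph::sample_pa(n, power = 1, m = max(1L, config$network_attachment),
                         directed = FALSE)
  deg <- igraph::degree(g)
  hubs <- order(deg, decreasing = TRUE)[1:2]
  if (!igraph::are_adjacent(g, hubs[1], hubs[2]))
    g <- igraph::add_edges(g, hubs)

  pool <- c(truth$lnc_background_ids, truth$mrna_background_ids)
  if (n - 2L > length(pool))
    stop("invalid config: not enough background genes for the network", call. = FALSE)
  ids <- character(n)
  ids[hubs] <- c(truth$signal_lnc_id, truth$signal_mrna_id)
  ids[-hubs] <- sample(pool, n - 2L)

  el <- igraph::as_edgelist(g, names = FALSE)
  data.frame(node1 = ids[el[, 1]], node2 = ids[el[, 2]],
             combined_score = sample(1000L, nrow(el), replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Generate a drug-target gene list containing the planted mRNA
#'
#' Emulates a curated disease-target list: the planted mRNA plus
#' `n_decoy_targets` background mRNAs (housekeeping references excluded),
#' in shuffled order. The default configuration yields 57 symbols.
#'
#' @inheritParams generate_network
#' @return character vector of gene symbols.
#' @export
generate_target_list <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  pool <- setdiff(truth$mrna_background_ids, REFERENCE_GENES)
  k <- config$n_decoy_targets
  if (k > length(pool))
    stop("invalid config: more decoy targets than background mRNAs", call. = FALSE)
  sample(c(truth$signal_mrna_id, sample(pool, k)))
}

#' Derive a qPCR relative-expression table from a simulated cohort
#'
#' Maps log2 abundance L to a cycle threshold Ct = 35 - L plus Gaussian
#' technical noise, then computes relative expression 2^(-dCt) with
#' dCt = Ct(gene) - Ct(reference). Doubling abundance lowers Ct by one
#' cycle. The reference gene must be a row of the cohort's matrices.
#'
#' @param cohort a [generate_cohort()] result.
#' @param genes gene ids to assay; defaults to the planted pair.
#' @param reference_gene housekeeping reference id (default `"RN18S"`).
#' @param tech_sd technical noise SD in Ct cycles.
#' @param seed RNG seed; defaults to the cohort seed + 3.
#' @return data.frame: `gene_id`, `sample_id`, `ct`, `delta_ct`, `rel_expr`.
#' @export
generate_qpcr <- function(cohort, genes = NULL, reference_gene = "RN18S",
                          tech_sd = 0.15, seed = cohort$config$seed + 3L) {
  stopifnot(inherits(cohort, "sim_cohort"))
  expr <- rbind(cohort$expr_lnc, cohort$expr_mrna)
  if (!reference_gene %in% rownames(expr))
    stop("reference gene '", reference_gene, "' not present in the cohort",
         call. = FALSE)
  if (is.null(genes))
    genes <- c(cohort$truth$signal_lnc_id, cohort$truth$signal_mrna_id)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stop("genes not present in the cohort: ", paste(missing, collapse = ", "),
         call. = FALSE)
  set.seed(seed)
  n <- ncol(expr)
  ct_of <- function(id) 35 - expr[id, ] + stats::rnorm(n, sd = tech_sd)
  ref_ct <- ct_of(reference_gene)
  out <- do.call(rbind, lapply(genes, function(id) {
    ct <- ct_of(id)
    data.frame(gene_id = id, sample_id = colnames(expr),
               ct = unname(ct), delta_ct = unname(ct - ref_ct),
               rel_expr = unname(2^-(ct - ref_ct)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pivot a qPCR table into a log2 relative-expression matrix
#'
#' Returns `log2(rel_expr)` (i.e. -dCt) as a genes x samples matrix, the
#' input shape expected by the classifier functions.
#'
#' @param qpcr a [generate_qpcr()] table.
#' @return numeric matrix, genes x samples.
#' @export
qpcr_matrix <- function(qpcr) {
  genes <- unique(qpcr$gene_id)
  samples <- unique(qpcr$sample_id)
  m <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, samples))
  m[cbind(match(qpcr$gene_id, genes), match(qpcr$sample_id, samples))] <-
    log2(qpcr$rel_expr)
  m
}

#' Simulate a complete study: cohort, network and target list
#'
#' @param config a [sim_config()].
#' @return list with `cohort`, `edges`, `targets`.
#' @export
simulate_study <- function(config) {
  cohort <- generate_cohort(config)
  list(cohort = cohort,
       edges = generate_network(cohort$truth, config),
       targets = generate_target_list(cohort$truth, config))
}
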