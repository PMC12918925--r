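#' Configuration for the synthetic scRNA-seq generator
#'
#' The generator emulates the statistical structure the pipelines rely on:
#' sparse cell-type expression programs shared across species, program
#' divergence growing with evolutionary distance (Brownian drift on
#' log-expression), negative-binomial counts with log-normal library sizes,
#' independent dropout, per-batch multiplicative artifacts, cluster-local and
#' class-imbalanced infection effects, and planted TF-to-target coupling.
#'
#' @param n_genes number of genes in the reference namespace.
#' @param cell_types data.frame with columns \code{name}, \code{n_cells}.
#' @param species data.frame with columns \code{name}, \code{divergence}
#'   (>= 0; the first row is the reference and must have divergence 0). Each
#'   type's log-program receives per-gene Gaussian drift with s.d.
#'   \code{divergence_drift_scale * divergence} (Brownian-like drift).
#' @param divergence_drift_scale proportionality constant converting a
#'   divergence value into the drift s.d. on log-expression. The default (2)
#'   is calibrated once so that a divergence of 1 erodes a substantial part
#'   of a default-strength program, making transfer quality and species
#'   similarity decay visibly across a unit-scale ladder.
#' @param program_sparsity fraction of genes elevated per type program.
#' @param program_strength log-scale elevation of program genes over baseline.
#' @param nb_dispersion negative-binomial size parameter (counts approach
#'   Poisson as it grows).
#' @param libsize_lognorm c(meanlog, sdlog) of per-cell library size.
#' @param dropout_rate probability a nonzero count is zeroed (technical
#'   dropout), in [0, 1).
#' @param n_batches,batch_sd number of batches and s.d. of per-batch gene-wise
#'   log-factors.
#' @param infection optional list(affected_types, effect_size, infected_frac)
#'   — per affected type, that fraction of its cells is marked infected and
#'   shifted on a common infection gene set; the sign of the shift alternates
#'   across affected types so the signature is local, not global.
#' @param tf_edges optional list of list(tf = gene index, targets = gene
#'   indices, coupling = real): each cell draws a latent TF activity which is
#'   added to the TF's log-expression and, scaled by \code{coupling}, to each
#'   target's.
#' @param private_frac fraction of each non-reference species' genes made
#'   species-private (absent from its ortholog map).
#' @param seed RNG seed; all randomness flows from it.
#' @return list of class \code{SyntheticConfig}.
#' @export
synthetic_config <- function(n_genes = 300,
                             cell_types = data.frame(
                               name = c("alpha", "beta", "gamma"),
                               n_cells = c(100, 100, 100)),
                             species = data.frame(name = "ref",
                                                  divergence = 0),
                             program_sparsity = 0.10,
                             program_strength = 2.0,
                             nb_dispersion = 2.0,
                             libsize_lognorm = c(log(2000), 0.3),
                             dropout_rate = 0.10,
                             n_batches = 1, batch_sd = 0,
                             infection = NULL, tf_edges = NULL,
                             private_frac = 0, divergence_drift_scale = 2,
                             seed = 0) {
  stopifnot(n_genes >= 10,
            program_sparsity > 0, program_sparsity < 1,
            program_strength > 0, nb_dispersion > 0,
            dropout_rate >= 0, dropout_rate < 1,
            n_batches >= 1, batch_sd >= 0,
            private_frac >= 0, private_frac < 1)
  species <- as.data.frame(species)
  if (species$divergence[1] != 0) {
    stop("first species is the reference and must have divergence 0")
  }
  if (any(species$divergence < 0)) stop("divergences must be >= 0")
  if (!is.null(infection)) {
    stopifnot(all(c("affected_types", "effect_size", "infected_frac") %in%
                    names(infection)),
              length(infection$infected_frac) ==
                length(infection$affected_types))
  }
  structure(list(n_genes = n_genes, cell_types = as.data.frame(cell_types),
                 species = species, program_sparsity = program_sparsity,
                 program_strength = program_strength,
                 nb_dispersion = nb_dispersion,
                 libsize_lognorm = libsize_lognorm,
                 dropout_rate = dropout_rate, n_batches = n_batches,
                 batch_sd = batch_sd, infection = infection,
                 tf_edges = tf_edges, private_frac = private_frac,
                 divergence_drift_scale = divergence_drift_scale,
                 seed = seed),
            class = "SyntheticConfig")
}

#' Generate a multi-species synthetic dataset with ground truth
#'
#' See \code{\link{synthetic_config}} for the generative model. Gene IDs are
#' \code{g1..gN} in the reference species and \code{<species>_g<i>} elsewhere;
#' the returned ortholog maps (species to reference, minus species-private
#' genes) recover the correspondence.
#'
#' @param cfg \code{\link{synthetic_config}}.
#' @return list with \code{datasets} (named list of
#'   \code{\link{expression_matrix}}, one per species, with meta columns
#'   cell_type, species, batch, disease_state), \code{omaps} (species to
#'   reference), \code{distances} (\code{\link{distance_table}} using the
#'   divergences), \code{truth} (programs, infection genes, tf edges).
#' @export
generate_synthetic <- function(cfg) {
  set.seed(cfg$seed)
  G <- cfg$n_genes
  types <- cfg$cell_types
  n_prog <- max(1L, round(cfg$program_sparsity * G))
  baseline <- stats::rnorm(G, 0, 1)
  programs <- sapply(seq_len(nrow(types)), function(t) {
    p <- baseline
    idx <- sample.int(G, n_prog)
    p[idx] <- p[idx] + cfg$program_strength
    p
  })
  colnames(programs) <- types$name
  infect_genes <- NULL
  if (!is.null(cfg$infection)) infect_genes <- sample.int(G, n_prog)
  ref_ids <- paste0("g", seq_len(G))
  datasets <- list(); omaps <- list()
  for (s in seq_len(nrow(cfg$species))) {
    sp_name <- cfg$species$name[s]
    div <- cfg$species$divergence[s]
    sp_programs <- programs +
      matrix(stats::rnorm(G * ncol(programs), 0,
                          cfg$divergence_drift_scale * div), G)
    n_cells <- sum(types$n_cells)
    cell_type <- rep(types$name, types$n_cells)
    batch <- sample(rep_len(seq_len(cfg$n_batches), n_cells))
    batch_fac <- matrix(stats::rnorm(G * cfg$n_batches, 0, cfg$batch_sd),
                        G, cfg$n_batches)
    disease <- rep("uninfected", n_cells)
    if (!is.null(cfg$infection)) {
      for (a in seq_along(cfg$infection$affected_types)) {
        idx <- which(cell_type == cfg$infection$affected_types[a])
        n_inf <- round(cfg$infection$infected_frac[a] * length(idx))
        if (n_inf > 0) disease[sample(idx, n_inf)] <- "infected"
      }
    }
    counts <- matrix(0, n_cells, G)
    L <- stats::rlnorm(n_cells, cfg$libsize_lognorm[1], cfg$libsize_lognorm[2])
    tf_act <- if (!is.null(cfg$tf_edges)) {   # one latent per edge per cell
      matrix(stats::rnorm(n_cells * length(cfg$tf_edges)), n_cells)
    }
    for (c_i in seq_len(n_cells)) {
      lp <- sp_programs[, cell_type[c_i]] + batch_fac[, batch[c_i]]
      if (disease[c_i] == "infected") {
        a <- match(cell_type[c_i], cfg$infection$affected_types)
        sign_a <- if (a %% 2 == 1) 1 else -1
        lp[infect_genes] <- lp[infect_genes] + sign_a * cfg$infection$effect_size
      }
      if (!is.null(cfg$tf_edges)) {
        for (e_i in seq_along(cfg$tf_edges)) {
          e <- cfg$tf_edges[[e_i]]
          lp[e$tf] <- lp[e$tf] + tf_act[c_i, e_i]
          lp[e$targets] <- lp[e$targets] + e$coupling * tf_act[c_i, e_i]
        }
      }
      p <- exp(lp - max(lp)); p <- p / sum(p)
      mu <- L[c_i] * p
      counts[c_i, ] <- stats::rnbinom(G, mu = mu, size = cfg$nb_dispersion)
    }
    if (cfg$dropout_rate > 0) {
      nz <- which(counts > 0)
      drop <- nz[stats::runif(length(nz)) < cfg$dropout_rate]
      counts[drop] <- 0
    }
    zero_rows <- rowSums(counts) == 0
    if (any(zero_rows)) {      # guarantee at least one transcript per cell
      for (c_i in which(zero_rows)) {
        counts[c_i, which.max(sp_programs[, cell_type[c_i]])] <- 1
      }
    }
    gene_ids <- if (s == 1) ref_ids else paste0(sp_name, "_g", seq_len(G))
    cell_ids <- paste0(sp_name, "_c", seq_len(n_cells))
    meta <- data.frame(cell_type = cell_type, species = sp_name,
                       batch = as.character(batch), disease_state = disease,
                       stringsAsFactors = FALSE)
    datasets[[sp_name]] <- expression_matrix(counts, gene_ids, cell_ids, meta)
    if (s > 1) {
      mapped <- seq_len(G)
      if (cfg$private_frac > 0) {
        mapped <- sort(sample.int(G, round((1 - cfg$private_frac) * G)))
      }
      omaps[[length(omaps) + 1L]] <- structure(
        list(source_gene = gene_ids[mapped], target_gene = ref_ids[mapped],
             source_species = sp_name,
             target_species = cfg$species$name[1]),
        class = "OrthologMap")
    }
  }
  distances <- distance_table(cfg$species$name, cfg$species$divergence,
                              reference = cfg$species$name[1])
  list(datasets = datasets, omaps = omaps, distances = distances,
       truth = list(programs = programs, infection_genes = infect_genes,
                    tf_edges = cfg$tf_edges, baseline = baseline))
}

#' Named benchmark fixtures with expected-property manifests
#'
#' Emits the fixed synthetic datasets the test suites run on, each paired
#' with a manifest of the property bounds the fixture is designed to meet.
#'
#' @param seed RNG seed.
#' @return named list of fixtures; each element has \code{data} and
#'   \code{manifest} (a JSON-serializable list of bounds).
#' @export
benchmark_suite <- function(seed = 0) {
  list(
    three_type_separable = list(
      data = generate_synthetic(synthetic_config(
        n_genes = 300,
        cell_types = data.frame(name = c("alpha", "beta", "gamma"),
                                n_cells = c(100, 100, 100)),
        program_strength = 2.5, dropout_rate = 0.1,
        n_batches = 2, batch_sd = 0.2, seed = seed)),
      manifest = list(min_self_transfer_macro_f1 = 0.95)),
    divergence_ladder = list(
      data = generate_synthetic(synthetic_config(
        n_genes = 300,
        cell_types = data.frame(name = c("alpha", "beta", "gamma"),
                                n_cells = c(60, 60, 60)),
        species = data.frame(name = c("ref", "sp1", "sp2", "sp3", "sp4"),
                             divergence = c(0, 0.2, 0.5, 1.0, 2.0)),
        program_strength = 2.5, dropout_rate = 0.1, seed = seed + 1)),
      manifest = list(max_rowwise_f1_divergence_spearman = 0)),
    local_infection = list(
      data = generate_synthetic(synthetic_config(
        n_genes = 300,
        cell_types = data.frame(
          name = paste0("type", 1:5),
          n_cells = rep(200, 5)),
        program_strength = 3.0, dropout_rate = 0.05,
        infection = list(affected_types = paste0("type", 1:3),
                         effect_size = 2.0,
                         infected_frac = c(0.5, 0.4, 0.3)),
        seed = seed + 2)),
      manifest = list(min_local_macro_f1 = 0.9)),
    tf_screen = list(
      data = generate_synthetic(synthetic_config(
        n_genes = 600,
        cell_types = data.frame(name = "cell", n_cells = 600),
        program_strength = 1.0, dropout_rate = 0.05,
        tf_edges = lapply(1:10, function(i)
          list(tf = i, targets = 10 + (i - 1) * 2 + 1:2, coupling = 1.5)),
        seed = seed + 3)),
      manifest = list(n_planted_edges = 20, n_screen_pairs = 200,
                      min_power = 0.7, max_fdr_factor = 2)),
    linear_blob = list(
      data = local({
        set.seed(seed + 4)
        basis <- qr.Q(qr(matrix(stats::rnorm(50 * 5), 50, 5)))
        scores <- matrix(stats::rnorm(800 * 5), 800, 5) %*%
          diag(c(5, 4, 3, 2, 1))
        list(points = scores %*% t(basis) +
               matrix(stats::rnorm(800 * 50, sd = 0.05), 800, 50))
      }),
      manifest = list(min_linearity = 0.95)),
    swiss_roll = list(
      data = swiss_roll(800, noise_sd = 0.05, seed = seed + 5),
      manifest = list(max_linearity_at_k10 = 0.8))
  )
}
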