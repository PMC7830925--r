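#' Simulation configuration for multi-model knockout studies
#'
#' Describes the shared design of a family of independent two-group
#' (knockout vs wild type) expression studies with a planted common
#' transcriptional program. Expression is simulated directly on the
#' normalized log2 scale; gene-wise variances are drawn from the scaled
#' inverse-chi-square prior that the empirical-Bayes moderation stage
#' assumes, so prior-recovery checks are well posed.
#'
#' @param n_models number of independent knockout models.
#' @param genes number of genes G per study.
#' @param samples_per_group samples per genotype group (n per WT and KO).
#' @param baseline_mean,baseline_sd log2 baseline intensity distribution.
#' @param prior_df,prior_var degrees of freedom d0 and scale s0^2 of the
#'   scaled inverse-chi-square variance prior: sigma_g^2 ~ s0^2 d0 / chisq(d0).
#' @param common_up,common_down numbers of genes perturbed in every model
#'   (up, down). The defaults keep the up/down asymmetry typical of fibrosis
#'   knockout models (many more commonly upregulated than downregulated
#'   genes).
#' @param specific_per_model genes perturbed in exactly one model (split
#'   evenly between up and down).
#' @param effect_size planted log2 fold change delta (>= 0; 0 gives null
#'   data for calibration checks).
#' @param planted_sets,decoy_sets numbers of gene sets loaded with planted
#'   genes vs drawn uniformly.
#' @param set_size integer range (min, max) of set sizes.
#' @param planted_set_fraction fraction of a planted set's members drawn
#'   from the common upregulated genes.
#' @param seed integer RNG seed; all generators are deterministic given it.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_models = 5L, genes = 2000L, samples_per_group = 4L,
                       baseline_mean = 7, baseline_sd = 1,
                       prior_df = 4, prior_var = 0.04,
                       common_up = 50L, common_down = 5L,
                       specific_per_model = 50L, effect_size = 1,
                       planted_sets = 5L, decoy_sets = 200L,
                       set_size = c(15L, 25L), planted_set_fraction = 0.8,
                       seed = 1L) {
  cfg <- list(n_models = as.integer(n_models), genes = as.integer(genes),
              samples_per_group = as.integer(samples_per_group),
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              prior_df = prior_df, prior_var = prior_var,
              common_up = as.integer(common_up),
              common_down = as.integer(common_down),
              specific_per_model = as.integer(specific_per_model),
              effect_size = effect_size,
              planted_sets = as.integer(planted_sets),
              decoy_sets = as.integer(decoy_sets),
              set_size = as.integer(set_size),
              planted_set_fraction = planted_set_fraction,
              seed = as.integer(seed))
  counts <- c(n_models = cfg$n_models, genes = cfg$genes,
              samples_per_group = cfg$samples_per_group,
              common_up = cfg$common_up, common_down = cfg$common_down,
              planted_sets = cfg$planted_sets)
  if (any(counts <= 0))
    stop("sim_config: counts must be positive: ",
         paste(names(counts)[counts <= 0], collapse = ", "))
  if (cfg$decoy_sets < 0 || cfg$specific_per_model < 0)
    stop("sim_config: decoy_sets and specific_per_model must be >= 0")
  if (cfg$prior_df <= 0 || cfg$prior_var <= 0)
    stop("sim_config: prior_df and prior_var must be positive")
  if (cfg$effect_size < 0) stop("sim_config: effect_size must be >= 0")
  if (cfg$baseline_sd < 0) stop("sim_config: baseline_sd must be >= 0")
  if (length(cfg$set_size) != 2L || any(cfg$set_size < 2L) ||
      cfg$set_size[1] > cfg$set_size[2])
    stop("sim_config: set_size must be an increasing pair of counts >= 2")
  if (cfg$planted_set_fraction <= 0 || cfg$planted_set_fraction > 1)
    stop("sim_config: planted_set_fraction must be in (0, 1]")
  planted <- cfg$common_up + cfg$common_down +
    cfg$n_models * cfg$specific_per_model
  if (planted > cfg$genes)
    stop("sim_config: common_up + common_down + n_models * specific_per_model",
         " (", planted, ") exceeds genes (", cfg$genes, ")")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", x$n_models, "models,", x$genes, "genes,",
      x$samples_per_group, "samples/group\n")
  cat("  planted: ", x$common_up, " common up, ", x$common_down,
      " common down, ", x$specific_per_model, " model-specific; delta = ",
      x$effect_size, " log2\n", sep = "")
  cat("  variance prior: d0 =", x$prior_df, ", s0^2 =", x$prior_var,
      "; seed =", x$seed, "\n")
  invisible(x)
}

#' Construct an expression study
#'
#' A single model's log2 expression matrix with its sample annotation.
#'
#' @param matrix numeric gene x sample matrix of log2 intensities, with
#'   row and column names.
#' @param group character or factor of per-sample genotype, levels WT/KO.
#' @param model_label free-text model identifier.
#' @param sex optional per-sample sex annotation (metadata only).
#' @return an object of class \code{expression_study}.
#' @export
expression_study <- function(matrix, group, model_label = "model",
                             sex = NULL) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("expression_study: 'matrix' must be a numeric matrix")
  if (anyNA(matrix)) stop("expression_study: missing values not allowed")
  if (is.null(rownames(matrix)) || anyDuplicated(rownames(matrix)))
    stop("expression_study: gene identifiers must be present and unique")
  if (is.null(colnames(matrix)))
    stop("expression_study: sample identifiers must be present")
  group <- factor(as.character(group), levels = c("WT", "KO"))
  if (length(group) != ncol(matrix) || anyNA(group))
    stop("expression_study: 'group' must label every sample as WT or KO")
  if (any(table(group) < 2L))
    stop("expression_study: need >= 2 samples per group")
  structure(list(matrix = matrix, genes = rownames(matrix),
                 samples = colnames(matrix), group = group,
                 model_label = model_label, sex = sex),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("Expression study '", x$model_label, "': ", nrow(x$matrix), " genes x ",
      ncol(x$matrix), " samples (", sum(x$group == "WT"), " WT, ",
      sum(x$group == "KO"), " KO)\n", sep = "")
  invisible(x)
}

#' Simulate a family of knockout-vs-wild-type expression studies
#'
#' Generates \code{n_models} independent studies sharing a planted common
#' program: each gene's value is
#' \code{mu_g + delta * I[planted, KO sample] * sign + eps}, with
#' \code{eps ~ N(0, sigma_g^2)} and \code{sigma_g^2 ~ s0^2 d0 / chisq(d0)}
#' drawn once per gene per study. The ground truth records the planted
#' gene lists, the names of the gene sets the set generator will load with
#' common upregulated genes, and the metabolic subsystem whose reactions
#' the toy network gates by common downregulated genes.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with components \code{studies} (list of
#'   \code{expression_study}) and \code{truth} (class \code{ground_truth}).
#' @export
simulate_studies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$genes
  n <- config$samples_per_group
  gene_ids <- sprintf("g%05d", seq_len(G))
  pool <- sample(gene_ids)
  take <- function(k) {
    if (k == 0L) return(character(0))
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  common_up <- take(config$common_up)
  common_down <- take(config$common_down)
  model_labels <- paste0("model", LETTERS[seq_len(config$n_models)])
  n_up_spec <- ceiling(config$specific_per_model / 2)
  specific_up <- specific_down <- vector("list", config$n_models)
  for (m in seq_len(config$n_models)) {
    specific_up[[m]] <- take(n_up_spec)
    specific_down[[m]] <- take(config$specific_per_model - n_up_spec)
  }
  studies <- vector("list", config$n_models)
  names(studies) <- model_labels
  for (m in seq_len(config$n_models)) {
    mu <- stats::rnorm(G, config$baseline_mean, config$baseline_sd)
    sigma2 <- config$prior_var * config$prior_df /
      stats::rchisq(G, config$prior_df)
    eps <- matrix(stats::rnorm(G * 2L * n, sd = sqrt(sigma2)),
                  nrow = G, ncol = 2L * n)
    x <- mu + eps
    rownames(x) <- gene_ids
    colnames(x) <- paste(model_labels[m],
                         rep(c("WT", "KO"), each = n),
                         rep(seq_len(n), times = 2L), sep = "_")
    group <- rep(c("WT", "KO"), each = n)
    ko <- group == "KO"
    up <- c(common_up, specific_up[[m]])
    dn <- c(common_down, specific_down[[m]])
    x[up, ko] <- x[up, ko] + config$effect_size
    x[dn, ko] <- x[dn, ko] - config$effect_size
    studies[[m]] <- expression_study(
      x, group, model_label = model_labels[m],
      sex = rep(c("F", "M"), length.out = 2L * n))
  }
  truth <- structure(list(
    common_up = common_up,
    common_down = common_down,
    model_up = stats::setNames(
      lapply(seq_len(config$n_models),
             function(m) c(common_up, specific_up[[m]])), model_labels),
    model_down = stats::setNames(
      lapply(seq_len(config$n_models),
             function(m) c(common_down, specific_down[[m]])), model_labels),
    planted_sets = stats::setNames(
      rep("pos", config$planted_sets),
      sprintf("planted_set_%02d", seq_len(config$planted_sets))),
    subsystem = c("Fatty acid beta-oxidation" = "down")),
    class = "ground_truth")
  list(studies = studies, truth = truth)
}

#' Simulate gene-set collections with planted enriched sets
#'
#' Planted sets draw \code{planted_set_fraction} of their members from the
#' commonly upregulated genes (random fillers for the rest); decoy sets are
#' drawn uniformly from all genes. Sets here may have as few as 2 members;
#' the size filter (>= 5 present members) is applied downstream by
#' \code{\link{build_collection}}.
#'
#' @param config a \code{\link{sim_config}}.
#' @param truth the \code{ground_truth} from \code{\link{simulate_studies}}.
#' @return a \code{\link{gene_set_collection}}.
#' @export
simulate_gene_sets <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  set.seed(config$seed + 1L)
  G <- config$genes
  gene_ids <- sprintf("g%05d", seq_len(G))
  n_sets <- config$planted_sets + config$decoy_sets
  sizes <- config$set_size[1] - 1L +
    sample.int(config$set_size[2] - config$set_size[1] + 1L, n_sets,
               replace = TRUE)
  if (any(sizes > G))
    stop("simulate_gene_sets: requested set size exceeds number of genes")
  sets <- vector("list", length(sizes))
  nm <- character(length(sizes))
  filler_pool <- setdiff(gene_ids, truth$common_up)
  for (i in seq_len(config$planted_sets)) {
    k <- min(max(2L, round(config$planted_set_fraction * sizes[i])),
             length(truth$common_up), sizes[i])
    sets[[i]] <- c(sample(truth$common_up, k),
                   sample(filler_pool, sizes[i] - k))
    nm[i] <- names(truth$planted_sets)[i]
  }
  for (j in seq_len(config$decoy_sets)) {
    i <- config$planted_sets + j
    sets[[i]] <- sample(gene_ids, sizes[i])
    nm[i] <- sprintf("decoy_set_%03d", j)
  }
  names(sets) <- nm
  gene_set_collection(sets, provenance = "custom")
}

#' Hand-curated toy liver metabolic network
#'
#' A fixed 14-metabolite, 21-reaction, 7-subsystem network sketching
#' hepatic central carbon metabolism as largely parallel modules: glucose
#' and fatty-acid uptake feed acetyl-CoA production through glycolysis
#' (capacity 5) and a four-step mitochondrial fatty acid beta-oxidation
#' chain (capacity 10); glutamine fuels an amino-acid / urea-cycle /
#' TCA-anaplerosis branch; a gluconeogenic recycle and a reversible
#' lactate shuttle are bounded tightly so their flux capacity does not
#' depend on the carbon supplied by beta-oxidation. The objective
#' maximizes acetyl-CoA output: with all genes active the optimum is 15;
#' silencing the beta-oxidation genes lowers it to 5, and only that
#' chain, its uptake and the objective drain lose capacity, so the
#' perturbation stays localized to the designated subsystem. The genes
#' gating the beta-oxidation reactions are renamed to the first four
#' commonly downregulated ground-truth genes, linking the planted
#' transcriptional program to the network.
#'
#' @param truth optional \code{ground_truth}; when supplied,
#'   \code{truth$common_down} must contain at least 4 gene identifiers.
#' @return a validated \code{metabolic_model}.
#' @export
toy_metabolic_model <- function(truth = NULL) {
  fao <- c("Cpt1a", "Acox1", "Hadha", "Acadm")
  if (!is.null(truth)) {
    stopifnot(inherits(truth, "ground_truth"))
    if (length(truth$common_down) < 4L)
      stop("toy_metabolic_model: need >= 4 common down genes to rename ",
           "the beta-oxidation GPRs")
    fao <- truth$common_down[1:4]
  }
  mets <- data.frame(
    id = c("glc_c", "g6p_c", "pyr_c", "lac_c", "accoa_c", "fa_c",
           "facoa_c", "facoa_m", "aacoa_m", "glu_c", "akg_c", "oaa_c",
           "ala_c", "urea_c"),
    compartment = "c", stringsAsFactors = FALSE)
  rxn <- function(id, name, subsystem, lb, ub, gpr, stoich)
    list(id = id, name = name, subsystem = subsystem, lb = lb, ub = ub,
         gpr = gpr, metabolites = stoich)
  reactions <- list(
    rxn("EX_glc", "Glucose uptake", "Exchange", 0, 10, "",
        c(glc_c = 1)),
    rxn("HEX1", "Hexokinase/glucokinase", "Glycolysis", 0, 5,
        "Hk1 or Gck", c(glc_c = -1, g6p_c = 1)),
    rxn("PYK", "Lower glycolysis (lumped)", "Glycolysis", 0, 5, "Pkm",
        c(g6p_c = -1, pyr_c = 1)),
    rxn("PDH", "Pyruvate dehydrogenase", "Glycolysis", 0, 5,
        "Pdha1 and Dlat", c(pyr_c = -1, accoa_c = 1)),
    rxn("G6PASE", "Glucose-6-phosphatase recycle", "Gluconeogenesis",
        0, 0.5, "G6pc", c(g6p_c = -1, glc_c = 1)),
    rxn("LDH", "Lactate dehydrogenase", "Glycolysis", -0.5, 0.5, "Ldha",
        c(pyr_c = -1, lac_c = 1)),
    rxn("EX_lac", "Lactate exchange", "Exchange", -0.5, 0.5, "",
        c(lac_c = -1)),
    rxn("EX_fa", "Fatty acid uptake", "Exchange", 0, 10, "",
        c(fa_c = 1)),
    rxn("FACOAL", "Fatty acyl-CoA ligase", "Fatty acid beta-oxidation",
        0, 10, fao[1], c(fa_c = -1, facoa_c = 1)),
    rxn("CPT1", "Carnitine shuttle", "Fatty acid beta-oxidation",
        0, 10, fao[2], c(facoa_c = -1, facoa_m = 1)),
    rxn("FAOX1", "Beta-oxidation spiral (lumped)",
        "Fatty acid beta-oxidation", 0, 10, fao[3],
        c(facoa_m = -1, aacoa_m = 1)),
    rxn("FAOX2", "Thiolytic cleavage", "Fatty acid beta-oxidation",
        0, 10, fao[4], c(aacoa_m = -1, accoa_c = 1)),
    rxn("EX_accoa", "Acetyl-CoA demand (objective)", "Exchange", 0, 1000,
        "", c(accoa_c = -1)),
    rxn("EX_gln", "Glutamine uptake (as glutamate)", "Exchange", 0, 3,
        "", c(glu_c = 1)),
    rxn("GLUD", "Glutamate dehydrogenase", "Amino acid metabolism", 0, 3,
        "Glud1", c(glu_c = -1, akg_c = 1)),
    rxn("ALT", "Alanine synthesis (lumped)", "Amino acid metabolism",
        0, 3, "Gpt", c(glu_c = -1, ala_c = 1)),
    rxn("EX_ala", "Alanine export", "Exchange", 0, 3, "",
        c(ala_c = -1)),
    rxn("ARG", "Urea production (lumped)", "Urea cycle", 0, 2, "Arg1",
        c(glu_c = -1, urea_c = 1)),
    rxn("EX_urea", "Urea export", "Exchange", 0, 2, "",
        c(urea_c = -1)),
    rxn("AKGDH", "Oxidative TCA branch (lumped)", "TCA cycle", 0, 3,
        "Sucla2 or Fh1", c(akg_c = -1, oaa_c = 1)),
    rxn("PEPCK", "Anaplerotic exit to pyruvate", "TCA cycle", 0, 3,
        "Pck1", c(oaa_c = -1, pyr_c = 1)))
  metabolic_model(mets, reactions, objective = "EX_accoa",
                  id = "toy_liver_gem")
}

#' Random toy network generator for oracle fuzzing
#'
#' Builds a random feasible chain-and-branch network: a linear spine from an
#' uptake to the objective sink guarantees a positive optimum, and random
#' branch reactions (with random small GPRs over a gene pool) add parallel
#' and diverting routes. Intended for stress-testing the gene-state solver
#' against brute-force enumeration, not for the main pipeline (the fixture
#' network of \code{\link{toy_metabolic_model}} is used there).
#'
#' @param n_genes size of the gene pool (gene ids \code{rg1..}).
#' @param n_extra number of random branch reactions beyond the spine.
#' @param spine_len number of internal spine metabolites (>= 2).
#' @param seed RNG seed.
#' @return a validated \code{metabolic_model}.
#' @export
random_toy_network <- function(n_genes = 6L, n_extra = 5L, spine_len = 4L,
                               seed = 1L) {
  stopifnot(spine_len >= 2L, n_genes >= 1L, n_extra >= 0L)
  set.seed(seed)
  genes <- paste0("rg", seq_len(n_genes))
  mets <- paste0("m", seq_len(spine_len))
  rand_gpr <- function() {
    k <- sample(0:2, 1L)
    if (k == 0L) return(sample(genes, 1L))
    g <- sample(genes, min(k + 1L, n_genes))
    paste(g, collapse = if (stats::runif(1) < 0.5) " and " else " or ")
  }
  reactions <- list(
    list(id = "UP", name = "uptake", subsystem = "Exchange", lb = 0,
         ub = round(stats::runif(1, 5, 10), 1), gpr = "",
         metabolites = c(m1 = 1)),
    list(id = "SINK", name = "objective sink", subsystem = "Exchange",
         lb = 0, ub = 1000, gpr = "",
         metabolites = stats::setNames(-1, mets[spine_len])))
  for (i in seq_len(spine_len - 1L)) {
    st <- stats::setNames(c(-1, 1), c(mets[i], mets[i + 1L]))
    reactions[[length(reactions) + 1L]] <-
      list(id = paste0("SP", i), name = paste0("spine ", i),
           subsystem = sample(c("SubA", "SubB", "SubC"), 1L),
           lb = 0, ub = round(stats::runif(1, 3, 9), 1), gpr = rand_gpr(),
           metabolites = st)
  }
  for (j in seq_len(n_extra)) {
    ends <- sample(seq_len(spine_len), 2L)
    st <- stats::setNames(c(-1, 1), mets[ends])
    reactions[[length(reactions) + 1L]] <-
      list(id = paste0("BR", j), name = paste0("branch ", j),
           subsystem = sample(c("SubA", "SubB", "SubC", "SubD"), 1L),
           lb = if (stats::runif(1) < 0.3) -round(stats::runif(1, 1, 4), 1)
                else 0,
           ub = round(stats::runif(1, 2, 8), 1), gpr = rand_gpr(),
           metabolites = st)
  }
  metabolic_model(data.frame(id = mets, compartment = "c",
                             stringsAsFactors = FALSE),
                  reactions, objective = "SINK",
                  id = paste0("random_net_", seed))
}
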