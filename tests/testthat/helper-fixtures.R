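# Small in-code fixtures shared across test files.

# Two-group study from explicit WT/KO matrices (genes x samples).
tiny_study <- function(wt, ko, label = "toy") {
  x <- cbind(wt, ko)
  if (is.null(rownames(x))) rownames(x) <- paste0("g", seq_len(nrow(x)))
  colnames(x) <- c(paste0("WT_", seq_len(ncol(wt))),
                   paste0("KO_", seq_len(ncol(ko))))
  expression_study(x, rep(c("WT", "KO"), c(ncol(wt), ncol(ko))),
                   model_label = label)
}

# Linear chain source -> A -> B -> sink with per-step capacities, for
# bottleneck FBA/FVA checks.
chain_model <- function(caps = c(10, 5, 8)) {
  rxn <- function(id, lb, ub, gpr, st, subsystem = "Chain")
    list(id = id, name = id, subsystem = subsystem, lb = lb, ub = ub,
         gpr = gpr, metabolites = st)
  metabolic_model(
    data.frame(id = c("A", "B"), compartment = "c",
               stringsAsFactors = FALSE),
    list(rxn("UP", 0, caps[1], "", c(A = 1), "Exchange"),
         rxn("R1", 0, caps[2], "gA", c(A = -1, B = 1)),
         rxn("SINK", 0, caps[3], "", c(B = -1), "Exchange")),
    objective = "SINK", id = "chain")
}

# Two parallel routes to the objective; gene gB gates the high-capacity
# branch. Used for gene-state matching edge cases.
parallel_model <- function(ub_a = 2, ub_b = 8) {
  rxn <- function(id, lb, ub, gpr, st, subsystem = "Core")
    list(id = id, name = id, subsystem = subsystem, lb = lb, ub = ub,
         gpr = gpr, metabolites = st)
  metabolic_model(
    data.frame(id = c("A", "B"), compartment = "c",
               stringsAsFactors = FALSE),
    list(rxn("UP", 0, ub_a + ub_b, "", c(A = 1), "Exchange"),
         rxn("RA", 0, ub_a, "gA", c(A = -1, B = 1)),
         rxn("RB", 0, ub_b, "gB", c(A = -1, B = 1)),
         rxn("SINK", 0, 1000, "", c(B = -1), "Exchange")),
    objective = "SINK", id = "parallel")
}

# Random DE input over the genes of a model plus optional off-network
# genes.
random_de_input <- function(model, n_extra = 2L) {
  genes <- c(model$genes, if (n_extra > 0L) paste0("x", seq_len(n_extra)))
  data.frame(gene_id = genes,
             d = sample(c(-1L, 0L, 1L), length(genes), replace = TRUE),
             w = round(runif(length(genes), 0, 10), 3),
             stringsAsFactors = FALSE)
}
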