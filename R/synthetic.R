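# Seeded generator of a schema-conformant mini evidence graph emulating a
# TCGA-like patient cohort (somatic mutations) plus a CTRP/CCLE-like
# cell-line program (drug response in a screen project, expression in a
# paired RNA project, same_as links between the two), with G2P associations
# wiring alleles to compounds, publications and phenotypes.
#
# Ground truth for the eight cookbook queries is tallied by direct
# bookkeeping as each element is emitted — never by running the query
# engine — so engine-vs-bookkeeping agreement is a real differential check.

#' Configuration for the synthetic mini evidence graph
#'
#' Defaults describe a small two-program cohort: a patient-like program
#' whose cases carry somatic callsets, and a cell-line-like program whose
#' first project holds a drug screen (EC50, AUC) and whose second project
#' holds expression assays, with cell lines mirrored across the two via
#' `same_as` links.
#'
#' @param seed Integer RNG seed; the same seed always yields a
#'   byte-identical serialized graph.
#' @param n_programs 0, 1 (patient-like only), or 2 (adds the
#'   cell-line-like program).
#' @param n_projects_per_program Projects per program (the cell-line
#'   program uses its first project as the drug screen and the second as
#'   the expression project).
#' @param n_cases_per_project Cases (patients / cell lines) per project.
#' @param tumor_fraction Probability a patient sample is `"Primary Tumor"`
#'   rather than `"Solid Tissue Normal"`.
#' @param n_genes Number of genes (Ensembl-style gids, also the dimension
#'   of each expression vector).
#' @param n_pathways,pathway_size_range Pathway count and member-count range.
#' @param mutations_per_case_range Somatic mutations per patient case.
#' @param caller_pool,p_mutect,p_other_caller Variant-caller method list on
#'   each callset-to-allele edge: the first pool entry (`"MUTECT"`) is
#'   included with `p_mutect`, the others with `p_other_caller`; at least
#'   one caller is always kept.
#' @param n_compounds,p_test Compound count and the probability a screen
#'   aliquot tested a given compound (aliquot *i* always tests compound
#'   *i*, so every compound is screened at least once when cases suffice).
#' @param n_g2p,n_publications Association and publication counts; the
#'   first association always links a project-1 tumor allele to compound 1,
#'   guaranteeing a non-empty literature-to-screen intersection.
#' @param p_same_as Probability a screen cell line is mirrored in the
#'   expression project (with paired directed `same_as` edges).
#' @param ec50_log10_range EC50 sampled log-uniform over this decade range
#'   (concentration, arbitrary micromolar-like units).
#' @param expression_meanlog,expression_sdlog Log-normal TPM parameters.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 42,
                             n_programs = 2,
                             n_projects_per_program = 2,
                             n_cases_per_project = 20,
                             tumor_fraction = 0.8,
                             n_genes = 50,
                             n_pathways = 10,
                             pathway_size_range = c(3, 12),
                             mutations_per_case_range = c(1, 15),
                             caller_pool = c("MUTECT", "MUSE", "VARSCAN"),
                             p_mutect = 0.7,
                             p_other_caller = 0.4,
                             n_compounds = 8,
                             p_test = 0.6,
                             n_g2p = 30,
                             n_publications = 12,
                             p_same_as = 0.5,
                             ec50_log10_range = c(-5, 0),
                             expression_meanlog = 2,
                             expression_sdlog = 1) {
  cfg <- list(seed = seed, n_programs = n_programs,
              n_projects_per_program = n_projects_per_program,
              n_cases_per_project = n_cases_per_project,
              tumor_fraction = tumor_fraction, n_genes = n_genes,
              n_pathways = n_pathways,
              pathway_size_range = pathway_size_range,
              mutations_per_case_range = mutations_per_case_range,
              caller_pool = caller_pool, p_mutect = p_mutect,
              p_other_caller = p_other_caller, n_compounds = n_compounds,
              p_test = p_test, n_g2p = n_g2p,
              n_publications = n_publications, p_same_as = p_same_as,
              ec50_log10_range = ec50_log10_range,
              expression_meanlog = expression_meanlog,
              expression_sdlog = expression_sdlog)
  counts <- c("n_programs", "n_projects_per_program", "n_cases_per_project",
              "n_genes", "n_pathways", "n_compounds", "n_g2p",
              "n_publications")
  for (nm in counts) {
    if (cfg[[nm]] < 0) stop(sprintf("%s must be >= 0", nm), call. = FALSE)
  }
  for (nm in c("tumor_fraction", "p_mutect", "p_other_caller", "p_test",
               "p_same_as")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      stop(sprintf("%s must be in [0, 1]", nm), call. = FALSE)
    }
  }
  if (n_programs > 2) {
    stop("n_programs is at most 2 (one patient-like, one cell-line-like)",
         call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

# Conventional gids of the default fixture, used as cookbook defaults.
syn_gids <- function() {
  list(
    patient_program = "Program:TCGA-SYN",
    patient_projects = c("Project:TCGA-SYN-BRCA", "Project:TCGA-SYN-LUAD",
                         "Project:TCGA-SYN-COAD", "Project:TCGA-SYN-PRAD",
                         "Project:TCGA-SYN-SKCM", "Project:TCGA-SYN-GBM"),
    cell_program = "Program:CTRP-SYN",
    screen_project = "Project:CTRP-SYN-Breast_Screen",
    rna_project = "Project:CTRP-SYN-Breast_RNA",
    compound = function(i) sprintf("Compound:CID%07d", i)
  )
}

syn_synonyms <- function(n) {
  pool <- c("ALPEVISTAT", "BELMURAFIB", "CETRAPANIB", "DOLUTREXANT",
            "EPOSERTIB", "FOLVESTRANT", "GENTAPANIB", "HERVOLIMUS")
  if (n <= length(pool)) pool[seq_len(n)] else {
    c(pool, sprintf("SYNDRUG%02d", seq_len(n - length(pool)) + length(pool)))
  }
}

syn_phenotypes <- function() {
  c("drug_sensitivity", "drug_resistance", "reduced_sensitivity",
    "increased_toxicity", "partial_response", "progressive_disease")
}

ens_gid <- function(i) sprintf("ENSG%011d", i)

with_preserved_rng <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Generate the synthetic mini evidence graph and its ground truth
#'
#' @param config A [synthetic_config()].
#' @return A list with `graph` (finalized, schema-conformant
#'   [`evigraph`][graph_new]), `ground_truth` (recorded expected results
#'   for the eight cookbook queries, computed by bookkeeping during
#'   generation), and `config`.
#' @export
#' @examples
#' fx <- generate_bmeg(synthetic_config(seed = 1, n_cases_per_project = 3,
#'                                      n_genes = 5, n_g2p = 4))
#' fx$graph
generate_bmeg <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_preserved_rng(config$seed, generate_bmeg_impl(config))
}

generate_bmeg_impl <- function(cfg) {
  has_mutations <- cfg$n_programs >= 1 && cfg$n_projects_per_program >= 1 &&
    cfg$n_cases_per_project >= 1 && max(cfg$mutations_per_case_range) > 0
  if (cfg$n_genes == 0 && has_mutations) {
    stop("degenerate config: mutations requested but n_genes is 0",
         call. = FALSE)
  }
  if (cfg$n_g2p > 0 && cfg$n_compounds == 0 && cfg$n_publications == 0) {
    stop("degenerate config: associations need compounds or publications",
         call. = FALSE)
  }
  ids <- syn_gids()
  g <- graph_new()

  ## -- genes and per-gene candidate variants ------------------------------
  gene_gids <- vapply(seq_len(cfg$n_genes), ens_gid, character(1))
  for (i in seq_len(cfg$n_genes)) {
    add_vertex(g, gene_gids[[i]], "Gene",
               list(symbol = sprintf("SYNG%d", i), ensembl_gene = gene_gids[[i]]))
  }
  # 3 recurrent candidate variants per gene; repeated draws of the same
  # candidate across cases share one Allele vertex
  n_cand <- cfg$n_genes * 3L
  cand <- vector("list", n_cand)
  for (i in seq_len(cfg$n_genes)) {
    for (k in 1:3) {
      bases <- sample(c("A", "C", "G", "T"), 2)
      cand[[(i - 1L) * 3L + k]] <- list(
        gene = i,
        chromosome = as.character(sample(22L, 1)),
        start = sample(10000L:100000000L, 1),
        ref = bases[[1]], alt = bases[[2]]
      )
    }
  }
  allele_gid_of <- function(ci) {
    v <- cand[[ci]]
    sprintf("Allele:%s:%d:%s:%s", v$chromosome, v$start, v$ref, v$alt)
  }
  alleles_created <- character(0)

  ## -- pathways -----------------------------------------------------------
  gene_pathways <- stats::setNames(vector("list", cfg$n_genes), gene_gids)
  pathway_sizes <- integer(0)
  pathway_gids <- character(0)
  for (p in seq_len(cfg$n_pathways)) {
    pgid <- sprintf("Pathway:SYN-PW%03d", p)
    add_vertex(g, pgid, "Pathway", list(name = sprintf("SYN-PW%03d", p)))
    size <- min(sample(cfg$pathway_size_range[[1]]:cfg$pathway_size_range[[2]],
                       1), cfg$n_genes)
    members <- if (size > 0) sample(cfg$n_genes, size) else integer(0)
    for (m in members) {
      add_edge(g, pgid, "genes", gene_gids[[m]])
      add_edge(g, gene_gids[[m]], "pathways", pgid)
      gene_pathways[[gene_gids[[m]]]] <-
        c(gene_pathways[[gene_gids[[m]]]], pgid)
    }
    pathway_gids <- c(pathway_gids, pgid)
    pathway_sizes <- c(pathway_sizes, length(members))
  }

  ## -- compounds, phenotypes, publications --------------------------------
  synonyms <- syn_synonyms(cfg$n_compounds)
  compound_gids <- vapply(seq_len(cfg$n_compounds), ids$compound, character(1))
  for (i in seq_len(cfg$n_compounds)) {
    add_vertex(g, compound_gids[[i]], "Compound",
               list(synonym = synonyms[[i]]))
  }
  phen_terms <- if (cfg$n_g2p > 0) syn_phenotypes() else character(0)
  phen_gids <- paste0("Phenotype:", phen_terms)
  for (i in seq_along(phen_terms)) {
    add_vertex(g, phen_gids[[i]], "Phenotype", list(term = phen_terms[[i]]))
  }
  pub_gids <- sprintf("Publication:ncbi.nlm.nih.gov/pubmed/SYN%07d",
                      seq_len(cfg$n_publications))
  for (pg in pub_gids) add_vertex(g, pg, "Publication", list(url = sub(
    "^Publication:", "", pg)))

  ## -- patient program: cohort tree + somatic callsets --------------------
  q1_tally <- new.env(parent = emptyenv())
  tumor_links <- list()        # (case_gid, allele_gid) per project-1 tumor
                               # mutation edge, in emission order
  n_mutect_tumor_edges <- 0L
  mutation_edges_project1 <- 0L

  if (cfg$n_programs >= 1) {
    add_vertex(g, ids$patient_program, "Program", list(name = "TCGA-SYN"))
    for (j in seq_len(cfg$n_projects_per_program)) {
      pj <- if (j <= length(ids$patient_projects)) {
        ids$patient_projects[[j]]
      } else {
        sprintf("Project:TCGA-SYN-P%02d", j)
      }
      add_vertex(g, pj, "Project",
                 list(project_id = sub("^Project:", "", pj)))
      add_edge(g, ids$patient_program, "projects", pj)
      for (ci in seq_len(cfg$n_cases_per_project)) {
        stem <- sprintf("%s-C%03d", sub("^Project:", "", pj), ci)
        case_gid <- paste0("Case:", stem)
        add_vertex(g, case_gid, "Case", list(submitter_id = stem))
        add_edge(g, pj, "cases", case_gid)
        tumor <- stats::runif(1) < cfg$tumor_fraction
        sample_gid <- paste0("Sample:", stem)
        add_vertex(g, sample_gid, "Sample", list(gdc_attributes = list(
          sample_type = if (tumor) "Primary Tumor" else "Solid Tissue Normal"
        )))
        add_edge(g, case_gid, "samples", sample_gid)
        add_edge(g, sample_gid, "case", case_gid)
        aliquot_gid <- paste0("Aliquot:", stem)
        add_vertex(g, aliquot_gid, "Aliquot")
        add_edge(g, sample_gid, "aliquots", aliquot_gid)
        callset_gid <- paste0("SomaticCallset:", stem)
        add_vertex(g, callset_gid, "SomaticCallset")
        add_edge(g, aliquot_gid, "somatic_callsets", callset_gid)
        n_mut <- sample(cfg$mutations_per_case_range[[1]]:
                          cfg$mutations_per_case_range[[2]], 1)
        n_mut <- min(n_mut, n_cand)
        picks <- if (n_mut > 0) sample(n_cand, n_mut) else integer(0)
        for (cix in picks) {
          agid <- allele_gid_of(cix)
          if (!(agid %in% alleles_created)) {
            alleles_created <- c(alleles_created, agid)
            v <- cand[[cix]]
            add_vertex(g, agid, "Allele", list(
              chromosome = v$chromosome, start = v$start,
              reference_bases = v$ref, alternate_bases = v$alt
            ))
          }
          methods <- character(0)
          for (m in seq_along(cfg$caller_pool)) {
            p <- if (m == 1) cfg$p_mutect else cfg$p_other_caller
            if (stats::runif(1) < p) {
              methods <- c(methods, cfg$caller_pool[[m]])
            }
          }
          if (length(methods) == 0) methods <- sample(cfg$caller_pool, 1)
          ens <- gene_gids[[cand[[cix]]$gene]]
          add_edge(g, callset_gid, "alleles", agid,
                   list(methods = as.list(methods), ensembl_gene = ens))
          if (j == 1 && tumor) {
            mutation_edges_project1 <- mutation_edges_project1 + 1L
            tumor_links[[length(tumor_links) + 1L]] <-
              list(case = case_gid, allele = agid)
            if ("MUTECT" %in% methods) {
              n_mutect_tumor_edges <- n_mutect_tumor_edges + 1L
              prev <- get0(ens, envir = q1_tally, ifnotfound = 0L)
              assign(ens, prev + 1L, envir = q1_tally)
            }
          }
        }
      }
    }
  }

  ## -- cell-line program: screen + expression projects --------------------
  screen_samples <- character(0)   # per screen case, in case order
  screen_aliquots <- character(0)
  line_ids <- character(0)
  mirrored <- logical(0)
  if (cfg$n_programs >= 2 && cfg$n_projects_per_program >= 1) {
    add_vertex(g, ids$cell_program, "Program", list(name = "CTRP-SYN"))
    scr <- ids$screen_project
    add_vertex(g, scr, "Project",
               list(project_id = sub("^Project:", "", scr)))
    add_edge(g, ids$cell_program, "projects", scr)
    for (ci in seq_len(cfg$n_cases_per_project)) {
      line <- sprintf("ACH-SYN-%03d", ci)
      line_ids <- c(line_ids, line)
      stem <- paste0("CTRP-SYN:", line)
      case_gid <- paste0("Case:", stem)
      add_vertex(g, case_gid, "Case", list(cellline_id = line))
      add_edge(g, scr, "cases", case_gid)
      sample_gid <- paste0("Sample:", stem)
      add_vertex(g, sample_gid, "Sample",
                 list(gdc_attributes = list(sample_type = "Cell Line")))
      add_edge(g, case_gid, "samples", sample_gid)
      add_edge(g, sample_gid, "case", case_gid)
      aliquot_gid <- paste0("Aliquot:", stem)
      add_vertex(g, aliquot_gid, "Aliquot")
      add_edge(g, sample_gid, "aliquots", aliquot_gid)
      screen_samples <- c(screen_samples, sample_gid)
      screen_aliquots <- c(screen_aliquots, aliquot_gid)
    }
    if (cfg$n_projects_per_program >= 2) {
      rna <- ids$rna_project
      add_vertex(g, rna, "Project",
                 list(project_id = sub("^Project:", "", rna)))
      add_edge(g, ids$cell_program, "projects", rna)
      for (ci in seq_along(line_ids)) {
        mirrored <- c(mirrored, stats::runif(1) < cfg$p_same_as)
        if (!mirrored[[ci]]) next
        line <- line_ids[[ci]]
        stem <- paste0("CCLE-SYN:", line)
        case_gid <- paste0("Case:", stem)
        add_vertex(g, case_gid, "Case", list(cellline_id = line))
        add_edge(g, rna, "cases", case_gid)
        scr_case <- paste0("Case:CTRP-SYN:", line)
        add_edge(g, scr_case, "same_as", case_gid)
        add_edge(g, case_gid, "same_as", scr_case)
        sample_gid <- paste0("Sample:", stem)
        add_vertex(g, sample_gid, "Sample",
                   list(gdc_attributes = list(sample_type = "Cell Line")))
        add_edge(g, case_gid, "samples", sample_gid)
        add_edge(g, sample_gid, "case", case_gid)
        aliquot_gid <- paste0("Aliquot:", stem)
        add_vertex(g, aliquot_gid, "Aliquot")
        add_edge(g, sample_gid, "aliquots", aliquot_gid)
      }
    }
  }

  ## -- drug responses on the screen project -------------------------------
  # responses for the conventional target compound, in traversal order
  q7_rows <- list()
  compound_tested_in_screen <- logical(cfg$n_compounds)
  target_compound <- if (cfg$n_compounds >= 1) compound_gids[[1]] else NA
  for (ci in seq_along(screen_aliquots)) {
    for (k in seq_len(cfg$n_compounds)) {
      tested <- stats::runif(1) < cfg$p_test
      if (ci == k) tested <- TRUE   # aliquot i always screens compound i
      if (!tested) next
      compound_tested_in_screen[[k]] <- TRUE
      ec50 <- signif(10^stats::runif(1, cfg$ec50_log10_range[[1]],
                                     cfg$ec50_log10_range[[2]]), 6)
      auc <- round(stats::runif(1, 0.2, 0.9), 4)
      submitter <- tolower(synonyms[[k]])
      dr_gid <- sprintf("DrugResponse:%s:CID%07d", line_ids[[ci]], k)
      add_vertex(g, dr_gid, "DrugResponse", list(
        ec50 = ec50, auc = auc, submitter_compound_id = submitter
      ))
      add_edge(g, screen_aliquots[[ci]], "drug_response", dr_gid)
      add_edge(g, dr_gid, "compounds", compound_gids[[k]])
      if (k == 1) {
        q7_rows[[length(q7_rows) + 1L]] <-
          list(screen_samples[[ci]], submitter, ec50)
      }
    }
  }
  for (k in seq_len(cfg$n_compounds)) {
    if (compound_tested_in_screen[[k]]) {
      add_edge(g, compound_gids[[k]], "projects", ids$screen_project)
    }
  }

  ## -- expression on the RNA project --------------------------------------
  expr_values <- list()   # line id -> values map
  for (ci in seq_along(line_ids)) {
    if (length(mirrored) < ci || !mirrored[[ci]]) next
    line <- line_ids[[ci]]
    vals <- round(stats::rlnorm(cfg$n_genes, cfg$expression_meanlog,
                                cfg$expression_sdlog), 4)
    vmap <- stats::setNames(as.list(vals), gene_gids)
    ge_gid <- paste0("GeneExpression:CCLE-SYN:", line)
    add_vertex(g, ge_gid, "GeneExpression",
               list(values = vmap, metric = "TPM"))
    add_edge(g, paste0("Aliquot:CCLE-SYN:", line), "gene_expressions", ge_gid)
    expr_values[[line]] <- vmap
  }

  ## -- G2P associations ----------------------------------------------------
  allele_assocs <- new.env(parent = emptyenv())  # allele gid -> assoc list
  for (a in seq_len(cfg$n_g2p)) {
    if (length(alleles_created) == 0) break
    agid <- if (a == 1 && length(tumor_links) > 0) {
      tumor_links[[1]]$allele
    } else {
      alleles_created[[sample(length(alleles_created), 1)]]
    }
    n_cmp <- if (cfg$n_compounds > 0) sample(min(3, cfg$n_compounds), 1) else 0
    cmp_idx <- if (n_cmp > 0) sort(sample(cfg$n_compounds, n_cmp)) else integer(0)
    if (a == 1 && cfg$n_compounds >= 1 && !(1L %in% cmp_idx)) {
      cmp_idx <- c(1L, cmp_idx[seq_len(max(0, n_cmp - 1))])
    }
    n_pub <- if (cfg$n_publications > 0) sample(min(3, cfg$n_publications), 1) else 0
    pub_idx <- if (n_pub > 0) sort(sample(cfg$n_publications, n_pub)) else integer(0)
    phen <- phen_gids[[sample(length(phen_gids), 1)]]
    assoc_gid <- sprintf("G2PAssociation:SYN-A%04d", a)
    add_vertex(g, assoc_gid, "G2PAssociation", list(
      description = sprintf("synthetic association %d", a),
      source = "synthetic"
    ))
    add_edge(g, agid, "g2p_associations", assoc_gid)
    for (pi in pub_idx) add_edge(g, assoc_gid, "publications", pub_gids[[pi]])
    for (ki in cmp_idx) add_edge(g, assoc_gid, "compounds", compound_gids[[ki]])
    add_edge(g, assoc_gid, "phenotypes", phen)
    rec <- list(pubs = pub_gids[pub_idx], compounds = compound_gids[cmp_idx])
    prev <- get0(agid, envir = allele_assocs, ifnotfound = list())
    assign(agid, c(prev, list(rec)), envir = allele_assocs)
  }

  finalize(g)

  ## -- ground truth from bookkeeping ---------------------------------------
  sorted_buckets_from_tally <- function(keys, counts) {
    ord <- order(-counts, keys, method = "radix")
    lapply(ord, function(i) list(key = keys[[i]], count = counts[[i]]))
  }

  q1_keys <- ls(q1_tally, sorted = FALSE)
  q1_counts <- vapply(q1_keys, function(k) get(k, envir = q1_tally),
                      integer(1), USE.NAMES = FALSE)
  q1_sorted <- if (length(q1_keys) > 0) {
    sorted_buckets_from_tally(q1_keys, q1_counts)
  } else {
    list()
  }
  gt_q1 <- result_aggregation(list(geneCount = q1_sorted))

  q2_genes <- vapply(q1_sorted, `[[`, character(1), "key")
  q2_tuples <- list()
  for (gg in q2_genes) {
    for (pw in gene_pathways[[gg]] %||% character(0)) {
      q2_tuples[[length(q2_tuples) + 1L]] <- list(gg, pw)
    }
  }
  gt_q2 <- result_render(q2_tuples, c("$gene._gid", "$._gid"))

  keep <- pathway_sizes > 0
  gt_q3 <- result_aggregation(list(pathwayGeneCount = if (any(keep)) {
    sorted_buckets_from_tally(pathway_gids[keep], pathway_sizes[keep])
  } else {
    list()
  }))

  q4_tally <- new.env(parent = emptyenv())
  q5_pairs <- new.env(parent = emptyenv())
  q5_tally <- new.env(parent = emptyenv())
  for (tl in tumor_links) {
    for (rec in get0(tl$allele, envir = allele_assocs, ifnotfound = list())) {
      for (pub in rec$pubs) {
        assign(pub, get0(pub, envir = q4_tally, ifnotfound = 0L) + 1L,
               envir = q4_tally)
      }
      for (cmp in rec$compounds) {
        pair <- paste(tl$case, cmp, sep = "\x1f")
        if (!exists(pair, envir = q5_pairs, inherits = FALSE)) {
          assign(pair, TRUE, envir = q5_pairs)
          assign(cmp, get0(cmp, envir = q5_tally, ifnotfound = 0L) + 1L,
                 envir = q5_tally)
        }
      }
    }
  }
  tally_result <- function(env, name) {
    keys <- ls(env, sorted = FALSE)
    counts <- vapply(keys, function(k) get(k, envir = env), integer(1),
                     USE.NAMES = FALSE)
    buckets <- if (length(keys) > 0) {
      sorted_buckets_from_tally(keys, counts)
    } else {
      list()
    }
    result_aggregation(stats::setNames(list(buckets), name))
  }
  gt_q4 <- tally_result(q4_tally, "pub")
  gt_q5 <- tally_result(q5_tally, "compound")

  q6_compounds <- vapply(gt_q5$rows$key, identity, character(1),
                         USE.NAMES = FALSE)
  q6_tuples <- list()
  for (cg in q6_compounds) {
    k <- match(cg, compound_gids)
    if (!is.na(k) && isTRUE(compound_tested_in_screen[[k]])) {
      q6_tuples[[length(q6_tuples) + 1L]] <- list(cg, synonyms[[k]])
    }
  }
  gt_q6 <- result_render(q6_tuples, c("_gid", "synonym"))

  gt_q7 <- result_render(q7_rows, c("$sample._gid",
                                    "$response.submitter_compound_id",
                                    "$response.ec50"))

  q8_samples <- unique(vapply(q7_rows, function(r) r[[1]], character(1)))
  q8_tuples <- list()
  for (s in q8_samples) {
    line <- sub("^Sample:CTRP-SYN:", "", s)
    vmap <- expr_values[[line]]
    if (!is.null(vmap)) {
      q8_tuples[[length(q8_tuples) + 1L]] <- list(s, vmap)
    }
  }
  gt_q8 <- result_render(q8_tuples, c("$sample._gid", "$exp._data.values"))

  gt <- structure(
    list(q1 = gt_q1, q2 = gt_q2, q3 = gt_q3, q4 = gt_q4, q5 = gt_q5,
         q6 = gt_q6, q7 = gt_q7, q8 = gt_q8),
    class = "evigraph_groundtruth"
  )
  attr(gt, "inputs") <- list(
    project_gid = if (cfg$n_programs >= 1) ids$patient_projects[[1]] else NA,
    gene_gids = as.list(q2_genes),
    compound_gids = as.list(q6_compounds),
    screen_project_id = sub("^Project:", "", ids$screen_project),
    program_gid = ids$cell_program,
    target_compound = target_compound,
    sample_gids = as.list(q8_samples)
  )
  attr(gt, "stats") <- list(
    n_mutect_tumor_edges = n_mutect_tumor_edges,
    mutation_edges_project1 = mutation_edges_project1,
    pathway_sizes = stats::setNames(as.list(pathway_sizes), pathway_gids)
  )
  list(graph = g, ground_truth = gt, config = cfg)
}

#' @export
print.evigraph_groundtruth <- function(x, ...) {
  sizes <- vapply(x, function(r) {
    switch(r$kind, render = length(r$rows), count = 1L, nrow(r$rows))
  }, integer(1))
  cat("<ground truth for cookbook queries>\n")
  for (nm in names(x)) {
    cat(sprintf("  %s: %s (%d rows)\n", nm, x[[nm]]$kind, sizes[[nm]]))
  }
  invisible(x)
}
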