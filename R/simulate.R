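# Synthetic data embodying the molecular similarity principle: compounds
# are built by decorating a pool of internal core scaffolds with small
# substituents, and per-cell-line sensitivity is assigned at the scaffold
# level (with compound-level label noise), so structurally similar
# compounds tend to share sensitivity labels. The raw-table generator then
# expands labeled pairs into replicate IC50/GI50/CC50 assay rows with
# configurable conflicts, counter-ion salts and off-type rows, exercising
# every curation rule.

# Core scaffolds: drug-like two-ring systems large enough that radius-8
# fingerprints of close analogs still overlap. All end at an append
# position, so `paste0(core, substituent)` is a valid SMILES.
.CORES <- c(
  "O=C(Nc1ccccc1)c1ccccc1",       # benzanilide
  "c1ccc2ccccc2c1",               # naphthalene
  "c1ccc(-c2ccccc2)cc1",          # biphenyl
  "O=C(Oc1ccccc1)c1ccccc1",       # phenyl benzoate
  "c1ccc2[nH]ccc2c1",             # indole
  "c1ccc2ncccc2c1",               # quinoline
  "O=S(=O)(c1ccccc1)Nc1ccccc1",   # benzenesulfonanilide
  "c1ccc(Cc2ccccc2)cc1",          # diphenylmethane
  "c1ccc(Oc2ccccc2)cc1",          # diphenyl ether
  "c1ccc(Nc2ccccn2)cc1",          # N-phenyl-2-aminopyridine
  "O=C(Cc1ccccc1)Nc1ccccc1",      # phenylacetanilide
  "c1ccc(-c2ccncc2)cc1",          # 4-phenylpyridine
  "c1ccc(N2CCNCC2)cc1",           # phenylpiperazine
  "O=C(NCc1ccccc1)c1ccccc1",      # N-benzylbenzamide
  "c1ccc(CN2CCOCC2)cc1",          # benzylmorpholine
  "O=C(c1ccccc1)c1ccccc1",        # benzophenone
  "c1ccc(CCc2ccccc2)cc1",         # bibenzyl
  "c1ccc(-c2ccco2)cc1",           # 2-phenylfuran
  "c1ccc(-c2cccs2)cc1",           # 2-phenylthiophene
  "O=C(Nc1ccccn1)c1ccccc1",       # N-(2-pyridyl)benzamide
  "c1ccc(Sc2ccccc2)cc1",          # diphenyl sulfide
  "c1ccc2c(c1)CCCC2",             # tetralin
  "O=C(Nc1ccc(F)cc1)c1ccccc1",    # 4-fluorobenzanilide
  "c1ccc(CNc2ccccc2)cc1"          # N-benzylaniline
)

# Small substituents appendable after a core.
.DECORATIONS <- c(
  "C", "CC", "CCC", "CCCC", "CO", "CCO", "CN", "CCN", "CCl", "CBr", "CF",
  "C(C)C", "CC(C)C", "COC", "CCF", "CCCl", "CS", "CSC", "CCS", "CCCO",
  "CCCN", "C(F)(F)F", "CC#N", "O", "N", "Cl", "Br", "F", "OC", "OCC",
  "CC(=O)O", "CC(=O)N", "CCOC", "C(=O)O"
)

#' Configuration for the synthetic data generator
#'
#' The defaults define the package's standard synthetic study conditions: a
#' scaffold-clustered library (12 scaffolds x 8 close analogs) screened
#' against 12 cell lines, scaffold-level sensitivity with probability 0.5,
#' 5% compound-level label noise, 20% replicate assays, 5% conflicting
#' assays, 10% salt-form SMILES and 2% off-type (EC50) rows.
#'
#' @param n_scaffolds number of core scaffolds (max 24 per pool).
#' @param n_per_scaffold analogs per scaffold (max 34).
#' @param n_cell_lines number of cell lines.
#' @param p_scaffold_active probability a (scaffold, cell line) pair is
#'   sensitive-prone.
#' @param label_noise probability a compound's label flips from its
#'   scaffold's tendency.
#' @param replicate_rate probability a pair gets an extra concordant assay
#'   row.
#' @param conflict_rate probability a pair gets an extra discordant assay
#'   row (curation will discard such pairs).
#' @param salt_rate probability an assay row reports the compound as a salt
#'   (counter-ion fragment added to the SMILES).
#' @param off_type_rate probability of an extra non-admitted (EC50) row.
#' @param min_sensitive_guarantee every cell line is topped up to at least
#'   this many sensitive compounds (0 disables).
#' @param scaffold_offset skip this many cores of the pool; lets a second
#'   library use scaffolds absent from the first (external validation).
#' @param seed integer seed; same config + seed gives identical output.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_scaffolds = 12L, n_per_scaffold = 8L,
                             n_cell_lines = 12L, p_scaffold_active = 0.5,
                             label_noise = 0.05, replicate_rate = 0.2,
                             conflict_rate = 0.05, salt_rate = 0.1,
                             off_type_rate = 0.02,
                             min_sensitive_guarantee = 10L,
                             scaffold_offset = 0L, seed = 1L) {
  cfg <- list(n_scaffolds = as.integer(n_scaffolds),
              n_per_scaffold = as.integer(n_per_scaffold),
              n_cell_lines = as.integer(n_cell_lines),
              p_scaffold_active = p_scaffold_active,
              label_noise = label_noise, replicate_rate = replicate_rate,
              conflict_rate = conflict_rate, salt_rate = salt_rate,
              off_type_rate = off_type_rate,
              min_sensitive_guarantee = as.integer(min_sensitive_guarantee),
              scaffold_offset = as.integer(scaffold_offset),
              seed = as.integer(seed))
  probs <- c("p_scaffold_active", "label_noise", "replicate_rate",
             "conflict_rate", "salt_rate", "off_type_rate")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0, 1]",
                                           call. = FALSE)
  }
  if (cfg$n_scaffolds < 1L || cfg$n_per_scaffold < 1L || cfg$n_cell_lines < 1L) {
    stop("counts must be >= 1", call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

#' Generate a scaffold-clustered compound library
#'
#' @param config a [generator_config()].
#' @return data.frame with `compound_id`, `smiles`, `scaffold`.
#' @export
generate_library <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$scaffold_offset + config$n_scaffolds > length(.CORES)) {
    stop("requested more scaffolds than the internal pool provides (",
         length(.CORES), ")", call. = FALSE)
  }
  if (config$n_per_scaffold > length(.DECORATIONS)) {
    stop("requested more analogs per scaffold than available decorations (",
         length(.DECORATIONS), ")", call. = FALSE)
  }
  cores <- .CORES[config$scaffold_offset + seq_len(config$n_scaffolds)]
  with_seed(config$seed, {
    rows <- do.call(rbind, lapply(seq_along(cores), function(s) {
      decos <- sample(.DECORATIONS, config$n_per_scaffold)
      data.frame(scaffold = sprintf("SCF%02d", config$scaffold_offset + s),
                 smiles = paste0(cores[s], decos), core = cores[s],
                 stringsAsFactors = FALSE)
    }))
    rows$compound_id <- sprintf("CPD%04d", seq_len(nrow(rows)))
    can <- canonical_smiles(rows$smiles)
    if (anyDuplicated(can)) {
      stop("internal error: duplicated structures in generated library")
    }
    rows[, c("compound_id", "smiles", "scaffold", "core")]
  })
}

#' Assign per-cell-line sensitivity labels to a library
#'
#' Each (scaffold, cell line) pair is drawn sensitive-prone with probability
#' `p_scaffold_active`; member compounds inherit the tendency, flipped with
#' probability `label_noise`. Cell lines short of
#' `min_sensitive_guarantee` sensitive compounds get whole scaffolds
#' promoted (deterministically under the seed) until the guarantee holds.
#'
#' @param library data.frame from [generate_library()].
#' @param config the same [generator_config()].
#' @return data.frame of truth pairs: `compound_id`, `cell_line_id`,
#'   `label`, `tendency`.
#' @export
generate_truth <- function(library, config) {
  stopifnot(inherits(config, "generator_config"))
  cells <- sprintf("CELL%02d", seq_len(config$n_cell_lines))
  scaffolds <- unique(library$scaffold)
  with_seed(config$seed + 1L, {
    active <- matrix(runif(length(scaffolds) * length(cells)) <
                       config$p_scaffold_active,
                     nrow = length(scaffolds),
                     dimnames = list(scaffolds, cells))
    truth <- do.call(rbind, lapply(cells, function(cl) {
      tend <- ifelse(active[library$scaffold, cl], "sensitive", "resistant")
      flip <- runif(nrow(library)) < config$label_noise
      lab <- ifelse(flip, ifelse(tend == "sensitive", "resistant",
                                 "sensitive"), tend)
      data.frame(compound_id = library$compound_id, cell_line_id = cl,
                 label = lab, tendency = tend, stringsAsFactors = FALSE)
    }))
    if (config$min_sensitive_guarantee > 0L) {
      for (cl in cells) {
        repeat {
          sel <- truth$cell_line_id == cl
          if (sum(truth$label[sel] == "sensitive") >=
              config$min_sensitive_guarantee) break
          inactive <- scaffolds[!active[, cl]]
          if (length(inactive) == 0L) {
            # all scaffolds active yet noise keeps the count short: unflip
            truth$label[sel & truth$tendency == "sensitive"] <- "sensitive"
            break
          }
          promote <- sample(inactive, 1L)
          active[promote, cl] <- TRUE
          mem <- sel & library$scaffold[match(truth$compound_id,
                                              library$compound_id)] == promote
          truth$label[mem] <- "sensitive"
          truth$tendency[mem] <- "sensitive"
        }
      }
    }
    rownames(truth) <- NULL
    truth
  })
}

.COUNTER_IONS <- c("Cl", "Br", "[Na+]", "[K+]", "O", "OS(=O)(=O)O")

#' Expand truth pairs into a raw activity table
#'
#' Sensitive pairs get concentrations drawn log-uniformly over
#' \[10 nM, 10 uM\] and resistant pairs over (10 uM, 1 mM\]; values are
#' reported in nM or uM at random. Replicate rows, conflicting rows,
#' salt-form SMILES and off-type (EC50) rows are injected at the configured
#' rates.
#'
#' @param truth data.frame from [generate_truth()].
#' @param library data.frame from [generate_library()].
#' @param config the same [generator_config()].
#' @return raw activity data.frame with the columns of
#'   [parse_activity_table()].
#' @export
generate_raw_table <- function(truth, library, config) {
  stopifnot(inherits(config, "generator_config"))
  smiles_of <- setNames(library$smiles, library$compound_id)
  with_seed(config$seed + 2L, {
    n <- nrow(truth)
    draw_conc <- function(lab, m) {
      lo <- ifelse(lab == "sensitive", 1e-8, 1.0000001e-5)
      hi <- ifelse(lab == "sensitive", 1e-5, 1e-3)
      exp(runif(m, log(lo), log(hi)))
    }
    base <- data.frame(
      compound_id = truth$compound_id, cell_line_id = truth$cell_line_id,
      label = truth$label, molar = draw_conc(truth$label, n),
      stringsAsFactors = FALSE)
    reps <- base[runif(n) < config$replicate_rate, , drop = FALSE]
    if (nrow(reps) > 0L) reps$molar <- draw_conc(reps$label, nrow(reps))
    confl <- base[runif(n) < config$conflict_rate, , drop = FALSE]
    if (nrow(confl) > 0L) {
      confl$label <- ifelse(confl$label == "sensitive", "resistant",
                            "sensitive")
      confl$molar <- draw_conc(confl$label, nrow(confl))
    }
    rows <- rbind(base, reps, confl)
    rows$assay_type <- sample(.ADMITTED_ASSAYS, nrow(rows), replace = TRUE)
    off <- rows[runif(nrow(rows)) < config$off_type_rate, , drop = FALSE]
    if (nrow(off) > 0L) off$assay_type <- "EC50"
    rows <- rbind(rows, off)
    rows$smiles <- unname(smiles_of[rows$compound_id])
    salted <- runif(nrow(rows)) < config$salt_rate
    if (any(salted)) {
      ions <- sample(.COUNTER_IONS, sum(salted), replace = TRUE)
      rows$smiles[salted] <- paste(rows$smiles[salted], ions, sep = ".")
    }
    in_nm <- runif(nrow(rows)) < 0.5
    rows$standard_value <- ifelse(in_nm, rows$molar * 1e9, rows$molar * 1e6)
    rows$standard_units <- ifelse(in_nm, "nM", "uM")
    rows$standard_relation <- "="
    out <- rows[, c("compound_id", "smiles", "cell_line_id", "assay_type",
                    "standard_value", "standard_units", "standard_relation")]
    out <- out[sample(nrow(out)), , drop = FALSE]  # shuffle row order
    rownames(out) <- NULL
    out
  })
}

#' Generate external-validation queries for a synthetic dataset
#'
#' Emulates the compounds that appear in a later release of an activity
#' database: mostly new analogs of scaffolds already present in the
#' reference (new decorations of the same cores, labels inheriting each
#' scaffold's sensitivity tendency with the configured label noise) plus
#' some entirely new chemotypes (cores absent from the reference, with
#' freshly drawn tendencies). None of the emitted structures occurs in the
#' reference library.
#'
#' @param sim a [simulate_dataset()] result (the reference conditions).
#' @param n_analogs_per_scaffold new decorations per reference scaffold.
#' @param n_new_scaffolds unseen cores to add.
#' @param n_per_new_scaffold compounds per unseen core.
#' @param seed integer seed.
#' @return list with `library` (compound_id, smiles, scaffold, core) and
#'   `pairs` (compound_id, smiles, cell_line_id, label).
#' @export
generate_external_queries <- function(sim, n_analogs_per_scaffold = 3L,
                                      n_new_scaffolds = 4L,
                                      n_per_new_scaffold = 4L, seed = 1L) {
  stopifnot(is.list(sim), all(c("library", "truth", "config") %in% names(sim)))
  cfg <- sim$config
  used_hi <- cfg$scaffold_offset + cfg$n_scaffolds
  if (used_hi + n_new_scaffolds > length(.CORES)) {
    stop("not enough unused cores in the pool for ", n_new_scaffolds,
         " new scaffolds", call. = FALSE)
  }
  cells <- sort(unique(sim$truth$cell_line_id))
  # scaffold-level tendencies of the reference truth
  tend <- unique(sim$truth[, c("compound_id", "cell_line_id", "tendency")])
  tend$scaffold <- sim$library$scaffold[match(tend$compound_id,
                                              sim$library$compound_id)]
  scaff_tend <- tapply(tend$tendency, list(tend$scaffold, tend$cell_line_id),
                       function(x) names(which.max(table(x))))
  with_seed(seed, {
    # analogs: unused decorations of each reference scaffold
    per_scaffold <- split(sim$library, sim$library$scaffold)
    analogs <- do.call(rbind, lapply(names(per_scaffold), function(sc) {
      lib <- per_scaffold[[sc]]
      used <- substring(lib$smiles, nchar(lib$core[1L]) + 1L)
      free <- setdiff(.DECORATIONS, used)
      take <- sample(free, min(n_analogs_per_scaffold, length(free)))
      data.frame(smiles = paste0(lib$core[1L], take), scaffold = sc,
                 core = lib$core[1L], new_scaffold = FALSE,
                 stringsAsFactors = FALSE)
    }))
    # new chemotypes: cores the reference never used
    new_cores <- .CORES[used_hi + seq_len(n_new_scaffolds)]
    novel <- do.call(rbind, lapply(seq_along(new_cores), function(s) {
      take <- sample(.DECORATIONS, n_per_new_scaffold)
      data.frame(smiles = paste0(new_cores[s], take),
                 scaffold = sprintf("NEW%02d", s), core = new_cores[s],
                 new_scaffold = TRUE, stringsAsFactors = FALSE)
    }))
    lib <- rbind(analogs, novel)
    lib$compound_id <- sprintf("EXT%04d", seq_len(nrow(lib)))
    new_tend <- matrix(
      ifelse(runif(n_new_scaffolds * length(cells)) < cfg$p_scaffold_active,
             "sensitive", "resistant"),
      nrow = n_new_scaffolds,
      dimnames = list(unique(novel$scaffold), cells))
    tend_all <- rbind(scaff_tend[, cells, drop = FALSE],
                      new_tend[, cells, drop = FALSE])
    pairs <- do.call(rbind, lapply(cells, function(cl) {
      t0 <- tend_all[cbind(lib$scaffold, cl)]
      flip <- runif(nrow(lib)) < cfg$label_noise
      data.frame(compound_id = lib$compound_id, smiles = lib$smiles,
                 cell_line_id = cl,
                 label = ifelse(flip, ifelse(t0 == "sensitive", "resistant",
                                             "sensitive"), t0),
                 stringsAsFactors = FALSE)
    }))
    rownames(pairs) <- NULL
    list(library = lib[, c("compound_id", "smiles", "scaffold", "core",
                           "new_scaffold")],
         pairs = pairs)
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [generate_library()], [generate_truth()] and
#' [generate_raw_table()] under one configuration.
#'
#' @param config a [generator_config()].
#' @return list with `library`, `truth`, `raw` and `config`.
#' @export
simulate_dataset <- function(config = generator_config()) {
  library <- generate_library(config)
  truth <- generate_truth(library, config)
  raw <- generate_raw_table(truth, library, config)
  list(library = library, truth = truth, raw = raw, config = config)
}
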