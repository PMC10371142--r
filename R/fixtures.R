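# Download-free synthetic fixtures with the statistical structure the
# pipeline assumes: SPPO-like structures assembled from the package's
# scaffolds, reactivation labels planted as a deterministic function of pair
# descriptors (flipped at a configurable noise rate), and logBB values drawn
# from a linear model on named descriptors plus Gaussian noise. The fixtures
# validate machinery, not chemistry.

# 19 R3 fragments: the observed diversity at the most variable position
FIXTURE_R3_POOL <- c(
  "*C", "*CC", "*CCC", "*C(C)C", "*CC(C)C", "*C(C)(C)C",
  "*OC", "*OCC", "*OC(C)C", "*CO",
  "*F", "*Cl", "*Br", "*I",
  "*C#N", "*[N+](=O)[O-]", "*C(F)(F)F", "*c1ccccc1", "*N(C)C"
)

# fragments pooled across the swappable positions R1/R2/R4/R5
FIXTURE_SWAP_POOL <- c("*C", "*CC", "*OC", "*F", "*Cl", "*Br", "*C(C)C")

# fused-ring "special" fragments at their observed position pairs
FIXTURE_SPECIALS <- list("R2&R3" = "*OCO*", "R3&R4" = "*OCCO*")

#' The synthetic generalization-probe organophosphate
#'
#' Phorate-oxon (O,O-diethyl S-(ethylthio)methyl phosphorothioate oxon), the
#' challenge used to probe prediction on an OP absent from training. Fixture
#' data for it is synthetic; the structure is the real metabolite.
#'
#' @return A one-row compound `data.frame` with id `"POX"`.
#' @export
fixture_probe_op <- function() {
  compound_records("POX", "CCOP(=O)(OCC)SCSCC", role = "OP",
                   name = "phorate-oxon (generalization probe)")
}

# deterministic, seeded assembly of n distinct SPPO-like molecules; every
# R3-pool fragment is guaranteed to appear at R3
sample_sppo_set <- function(n_sppos, seed) {
  set.seed(seed)
  r3_pool <- FIXTURE_R3_POOL
  swap <- c(H_FRAG, FIXTURE_SWAP_POOL)
  # hydrogen dominates the swappable positions, as in sparsely substituted
  # synthesis series
  swap_p <- c(0.6, rep(0.4 / length(FIXTURE_SWAP_POOL),
                       length(FIXTURE_SWAP_POOL)))
  n_special <- max(0L, min(round(0.05 * n_sppos), n_sppos - length(r3_pool)))
  decs <- vector("list", n_sppos)
  seen <- new.env(parent = emptyenv())
  i <- 1L
  tries <- 0L
  while (i <= n_sppos) {
    tries <- tries + 1L
    if (tries > 50L * n_sppos) {
      stop("fragment pools cannot produce ", n_sppos, " distinct molecules",
           call. = FALSE)
    }
    sc <- sample(SCAFFOLD_IDS, 1L)
    n <- sample(3:5, 1L)
    rg <- character(0)
    if (i <= n_special) {
      pair <- sample(names(FIXTURE_SPECIALS), 1L)
      rg[[pair]] <- FIXTURE_SPECIALS[[pair]]
      open <- setdiff(POSITIONS, strsplit(pair, "&", fixed = TRUE)[[1]])
    } else {
      # cycle the R3 whitelist so all 19 fragments are observed there
      rg[["R3"]] <- r3_pool[((i - n_special - 1L) %% length(r3_pool)) + 1L]
      open <- c("R1", "R2", "R4", "R5")
    }
    for (p in open) {
      f <- sample(swap, 1L, prob = swap_p)
      if (f != H_FRAG) rg[[p]] <- f
    }
    d <- decomposition(sprintf("sppo_%03d", i), sc, n, rg)
    # mirror-normalized key: the phenoxy ring's two orientations (R1<->R5,
    # R2<->R4, R2&R3 <-> R3&R4) give the same molecule
    full <- stats::setNames(rep(H_FRAG, 5L), POSITIONS)
    for (k in names(d$rgroups)) {
      for (p in strsplit(k, "&", fixed = TRUE)[[1]]) full[[p]] <- d$rgroups[[k]]
    }
    tup <- paste(full, collapse = ";")
    tup_rev <- paste(rev(full), collapse = ";")
    key <- paste(d$scaffold_id, d$n, min(tup, tup_rev), sep = "|")
    if (exists(key, envir = seen, inherits = FALSE)) next
    assign(key, TRUE, envir = seen)
    decs[[i]] <- d
    i <- i + 1L
  }
  smiles <- reassemble(decs)
  if (anyDuplicated(smiles)) {
    # distinct assignments virtually always give distinct molecules; if two
    # collide, fail loudly rather than silently shrinking the set
    stop("assignment sampling produced duplicate molecules", call. = FALSE)
  }
  list(decs = decs,
       sppos = compound_records(vapply(decs, function(d) d$sppo_id,
                                       character(1)),
                                smiles, role = "SPPO"))
}

#' Generate the synthetic SPPO reactivation fixture
#'
#' Assembles `n_sppos` distinct SPPO-like molecules from the built-in
#' scaffold and fragment pools (all 19 R3-pool fragments observed at R3) and
#' emits one reactivation measurement per (SPPO, OP) pairing. True classes
#' are planted deterministically: pairs are ranked by a fixed rule on named
#' descriptors (SPPO TPSA and logP, OP logP) and assigned to No/Low/High by
#' the class quota; each label is then flipped with probability `noise_rate`;
#' finally a percent is drawn from the class-conditional distributions
#' No ~ U(-0.4, 0.4), Low ~ U(5, 38), High ~ U(45, 95), which sit safely away
#' from the bin boundaries.
#'
#' @param n_sppos Number of reactivators (default 149, giving 596 pairs over
#'   the default 4-OP panel — the assembled dataset's scale).
#' @param ops OP compound `data.frame` (default: the four assay OPs PIMP,
#'   NEMP, PXN, DFP).
#' @param class_fractions Target class mix; the default reproduces the
#'   260/226/110 No/Low/High composition of the assembled assay dataset.
#' @param noise_rate Label-flip probability in [0, 0.5).
#' @param seed Mandatory integer seed; output is reproducible from it alone.
#' @return List: `sppos`, `ops`, `measurements` (`sppo_id`, `op_id`,
#'   `reactivation_percent`), `decompositions`, and `ledger` (true and
#'   emitted classes per pair, the planted rule description, quota, seed).
#' @export
generate_sppo_fixture <- function(n_sppos = 149L,
                                  ops = op_panel(c("PIMP", "NEMP", "PXN",
                                                   "DFP")),
                                  class_fractions = c(No = 260, Low = 226,
                                                      High = 110) / 596,
                                  noise_rate = 0, seed) {
  if (missing(seed)) stop("seed is mandatory for fixtures", call. = FALSE)
  stopifnot(noise_rate >= 0, noise_rate < 0.5,
            all(sort(names(class_fractions)) == sort(REACTIVATION_CLASSES)))
  set_obj <- sample_sppo_set(n_sppos, seed)
  sppos <- set_obj$sppos

  grid <- expand.grid(sppo_id = sppos$id, op_id = ops$id,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$sppo_id, grid$op_id), , drop = FALSE]
  rownames(grid) <- NULL
  n_pairs <- nrow(grid)

  chem_s <- descriptor_matrix(sppos)
  chem_o <- descriptor_matrix(ops)
  z <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  # the planted rule: high-TPSA, low-logP reactivators do best, harder
  # (more lipophilic) challenges are reactivated less
  score <- z(chem_s[grid$sppo_id, "TPSA"]) -
    z(chem_s[grid$sppo_id, "MolLogP"]) -
    0.5 * z(chem_o[grid$op_id, "MolLogP"])

  quota <- round(class_fractions[REACTIVATION_CLASSES] * n_pairs)
  quota[1] <- n_pairs - sum(quota[-1])  # largest-remainder on "No"
  ranked <- order(score, decreasing = TRUE)
  true_class <- character(n_pairs)
  true_class[ranked[seq_len(quota[["High"]])]] <- "High"
  true_class[ranked[quota[["High"]] + seq_len(quota[["Low"]])]] <- "Low"
  true_class[ranked[quota[["High"]] + quota[["Low"]] +
                      seq_len(quota[["No"]])]] <- "No"

  set.seed(seed + 1L)
  emitted <- true_class
  flip <- which(runif(n_pairs) < noise_rate)
  for (i in flip) {
    emitted[i] <- sample(setdiff(REACTIVATION_CLASSES, true_class[i]), 1L)
  }
  percent <- numeric(n_pairs)
  for (cls in REACTIVATION_CLASSES) {
    idx <- which(emitted == cls)
    percent[idx] <- switch(cls,
      No = runif(length(idx), -0.4, 0.4),
      Low = runif(length(idx), 5, 38),
      High = runif(length(idx), 45, 95))
  }
  measurements <- data.frame(grid,
                             reactivation_percent = round(percent, 3),
                             stringsAsFactors = FALSE)
  list(
    sppos = sppos, ops = ops, measurements = measurements,
    decompositions = set_obj$decs,
    ledger = list(
      true_class = data.frame(grid, class = true_class,
                              emitted_class = emitted,
                              stringsAsFactors = FALSE),
      rule = paste("rank of z(sppo TPSA) - z(sppo MolLogP) -",
                   "0.5 z(op MolLogP), quota-binned"),
      rule_descriptors = c("sppo__TPSA", "sppo__MolLogP", "op__MolLogP"),
      quota = quota, noise_rate = noise_rate, seed = seed
    )
  )
}

# diverse drug-like molecules from two-slot templates; deterministic order
logbb_candidate_smiles <- function(n_needed) {
  templates <- c(
    "c1cc(%s)ccc1%s",            # benzenes
    "c1cc(%s)cnc1%s",            # pyridines
    "c1cc(%s)ccc1O%s",           # aryl ethers
    "C1CCC(%s)CC1%s",            # cyclohexanes
    "c1ccc(C(=O)N(C)%s)cc1%s",   # benzamides
    "c1ccc2cc(%s)ccc2c1%s"       # naphthalenes
  )
  subs <- c("C", "CC", "CCC", "C(C)C", "CO", "CCO", "OC", "OCC", "N(C)C",
            "CN(C)C", "F", "Cl", "Br", "C#N", "C(F)(F)F", "C(=O)OC",
            "C(=O)NC", "S(C)(=O)=O", "[N+](=O)[O-]", "CCN(C)C")
  combos <- expand.grid(t = templates, a = subs, b = subs,
                        stringsAsFactors = FALSE)
  raw <- sprintf(combos$t, combos$a, combos$b)
  canon <- unique(canonical_smiles(raw, strict = FALSE))
  canon <- canon[!is.na(canon)]
  if (length(canon) < n_needed) {
    stop("requested size exceeds the generable diversity (",
         length(canon), " distinct molecules available)", call. = FALSE)
  }
  canon
}

#' Generate the synthetic logBB fixture
#'
#' Enumerates diverse drug-like molecules from built-in two-slot templates
#' and assigns each a logBB from a linear model on four named descriptors —
#' logP (positive weight), TPSA, molecular weight and hydrogen-bond-donor
#' count (negative weights), the canonical drivers of brain penetration —
#' plus Gaussian noise. The intercept is chosen so the two classes at
#' threshold 0 are roughly balanced, mirroring the composition of curated
#' logBB regression sets.
#'
#' @param n Number of molecules (default 1058, the regression-set scale).
#' @param coefficients Named weights on `MolLogP`, `TPSA`, `MolWt`,
#'   `NumHDonors`.
#' @param noise_sd Gaussian noise standard deviation (log units).
#' @param seed Mandatory integer seed.
#' @return List: `data` (`compound_id`, `smiles`, `logBB`), `ledger`
#'   (coefficients incl. the chosen intercept, noise_sd, seed, and the
#'   noiseless linear part per molecule).
#' @export
generate_logbb_fixture <- function(n = 1058L,
                                   coefficients = c(MolLogP = 0.5,
                                                    TPSA = -0.016,
                                                    MolWt = -0.003,
                                                    NumHDonors = -0.2),
                                   noise_sd = 0.3, seed) {
  if (missing(seed)) stop("seed is mandatory for fixtures", call. = FALSE)
  stopifnot(noise_sd >= 0)
  pool <- logbb_candidate_smiles(n)
  set.seed(seed)
  smiles <- sample(pool, n)
  ids <- sprintf("bbb_%04d", seq_len(n))
  chem <- descriptor_matrix(stats::setNames(
    data.frame(ids, smiles, "UNKNOWN", NA_character_,
               stringsAsFactors = FALSE),
    c("id", "smiles", "role", "name")))
  lin <- as.numeric(chem[, names(coefficients), drop = FALSE] %*%
                      coefficients)
  intercept <- -stats::median(lin)
  logbb <- intercept + lin + rnorm(n, 0, noise_sd)
  list(
    data = data.frame(compound_id = ids, smiles = smiles,
                      logBB = logbb, stringsAsFactors = FALSE),
    ledger = list(coefficients = c(intercept = intercept, coefficients),
                  noise_sd = noise_sd, seed = seed,
                  linear_part = intercept + lin)
  )
}

#' Write a fixture to the on-disk schema the ingesters read
#'
#' Emits the same CSV schemas as the real inputs plus a `ledger.json` holding
#' the generator's ground truth.
#'
#' @param fixture A result of [generate_sppo_fixture()] or
#'   [generate_logbb_fixture()].
#' @param dir Destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(fixture$measurements)) {
    write.csv(fixture$sppos, file.path(dir, "sppos.csv"), row.names = FALSE)
    write.csv(fixture$ops, file.path(dir, "ops.csv"), row.names = FALSE)
    write.csv(fixture$measurements, file.path(dir, "reactivation.csv"),
              row.names = FALSE)
  } else {
    write.csv(fixture$data, file.path(dir, "logbb.csv"), row.names = FALSE)
  }
  jsonlite::write_json(fixture$ledger, file.path(dir, "ledger.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
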