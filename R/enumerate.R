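# Rule-constrained combinatorial enumeration of the virtual SPPO library.
#
# The three generation rules: (1) linker length n restricted to 3, 4 or 5;
# (2) R3 restricted to the fragments observed at R3 in the input set (the
# position with the highest observed diversity); (3) R1, R2, R4 and R5 drawn
# from the pooled set of fragments observed at any of those four positions
# (hydrogen always included). Fused-ring "special" fragments occupy their
# observed position pair and consume the R3 slot.

#' Enumeration rules for the virtual library
#'
#' @param r3_whitelist Dummy-capped fragments allowed at R3 (`"H"` permitted).
#' @param swap_pool Fragments pooled across R1/R2/R4/R5; hydrogen is always
#'   added if absent.
#' @param n_values Allowed linker lengths; values outside 3..5 are an error
#'   unless `allow_any_n = TRUE`.
#' @param scaffolds Scaffold ids to enumerate over.
#' @param specials Named list over `"R2&R3"` / `"R3&R4"` of two-attachment
#'   fused-ring fragments; each occupies its pair (consuming R3) when used.
#' @param allow_any_n Override the 3..5 linker rule.
#' @return An object of class `enumeration_rules`.
#' @export
enumeration_rules <- function(r3_whitelist, swap_pool = character(),
                              n_values = 3:5,
                              scaffolds = sppo_scaffolds(),
                              specials = list(),
                              allow_any_n = FALSE) {
  n_values <- sort(unique(as.integer(n_values)))
  if (!length(n_values)) stop("n_values is empty", call. = FALSE)
  if (!all(n_values %in% 3:5) && !allow_any_n) {
    stop("linker length rule allows only n in {3, 4, 5}; set ",
         "allow_any_n = TRUE to override", call. = FALSE)
  }
  r3_whitelist <- unique(as.character(r3_whitelist))
  if (!length(r3_whitelist)) stop("empty R3 whitelist", call. = FALSE)
  swap_pool <- unique(c(H_FRAG, as.character(swap_pool)))
  scaffolds <- match.arg(scaffolds, SCAFFOLD_IDS, several.ok = TRUE)
  bad <- setdiff(names(specials), SPECIAL_PAIRS)
  if (length(bad)) stop("specials must be named by ",
                        paste(SPECIAL_PAIRS, collapse = " / "), call. = FALSE)
  structure(list(r3_whitelist = r3_whitelist, swap_pool = swap_pool,
                 n_values = n_values, scaffolds = scaffolds,
                 specials = specials),
            class = "enumeration_rules")
}

#' Derive enumeration rules from a fragment pool
#'
#' Applies the three generation rules to the pool returned by
#' [fragment_pool()]: R3 keeps only fragments observed there, the swap pool
#' is the union over R1/R2/R4/R5, and fused pairs keep their observed pair.
#'
#' @param pool A `data.frame` from [fragment_pool()].
#' @param n_values,scaffolds Passed to [enumeration_rules()].
#' @param include_specials Enumerate fused-ring fragments at their observed
#'   pairs (default `TRUE`).
#' @return An `enumeration_rules` object.
#' @export
rules_from_pool <- function(pool, n_values = 3:5,
                            scaffolds = sppo_scaffolds(),
                            include_specials = TRUE) {
  obs <- strsplit(pool$positions_observed, ",", fixed = TRUE)
  at <- function(p) pool$smiles[vapply(obs, function(x) p %in% x, logical(1))]
  r3 <- setdiff(at("R3"), H_FRAG)
  swap <- setdiff(unique(unlist(lapply(c("R1", "R2", "R4", "R5"), at))),
                  H_FRAG)
  specials <- list()
  if (include_specials) {
    for (pair in SPECIAL_PAIRS) {
      fr <- at(pair)
      if (length(fr)) specials[[pair]] <- fr
    }
  }
  enumeration_rules(r3_whitelist = if (length(r3)) r3 else H_FRAG,
                    swap_pool = swap, n_values = n_values,
                    scaffolds = scaffolds, specials = specials)
}

# all (R3-mode, swap-position) block definitions for one rules object:
# each block is a list(key = rgroup name for the R3 slot, frags = choices,
# open = the swap positions left to fill)
r3_blocks <- function(rules) {
  blocks <- list(list(key = "R3", frags = rules$r3_whitelist,
                      open = c("R1", "R2", "R4", "R5")))
  for (pair in names(rules$specials)) {
    blocks[[length(blocks) + 1L]] <- list(
      key = pair, frags = rules$specials[[pair]],
      open = setdiff(POSITIONS, strsplit(pair, "&", fixed = TRUE)[[1]]))
  }
  blocks
}

#' Count the raw (pre-deduplication) combination space
#'
#' @param rules An `enumeration_rules` object.
#' @return Number of (scaffold, n, assignment) tuples the rules permit.
#' @export
count_combinations <- function(rules) {
  stopifnot(inherits(rules, "enumeration_rules"))
  per_sn <- sum(vapply(r3_blocks(rules), function(b) {
    length(b$frags) * length(rules$swap_pool)^length(b$open)
  }, numeric(1)))
  length(rules$scaffolds) * length(rules$n_values) * per_sn
}

#' Enumerate the deduplicated virtual candidate library
#'
#' Streams through every (scaffold, n, assignment) tuple the rules permit in
#' chunks, canonicalizes each assembled molecule in batches, and keeps the
#' first occurrence of each canonical SMILES. Optionally validates that every
#' candidate carries exactly one pyridinium ring and at least one oxime.
#'
#' @param rules An `enumeration_rules` object.
#' @param exclude Canonical SMILES to leave out (typically the input SPPOs,
#'   since the library is of *new* variations).
#' @param id_prefix Candidate ids are `<prefix>_000001` etc.
#' @param chunk_size Molecules canonicalized per backend batch.
#' @param max_combinations Guard against runaway spaces (error if exceeded).
#' @param validate Run the structural sanity screen (default `TRUE`).
#' @return A `candidate_library`: `records` data.frame (`id`, `smiles`,
#'   `scaffold_id`, `n`, `assignment` as JSON) plus a `stats` list.
#' @export
enumerate_candidates <- function(rules, exclude = character(),
                                 id_prefix = "cand", chunk_size = 512L,
                                 max_combinations = 2e6,
                                 validate = TRUE) {
  stopifnot(inherits(rules, "enumeration_rules"))
  total <- count_combinations(rules)
  if (total > max_combinations) {
    stop("rule space has ", format(total, big.mark = ","),
         " combinations, above max_combinations = ",
         format(max_combinations, big.mark = ","), call. = FALSE)
  }
  seen <- new.env(parent = emptyenv())
  for (s in exclude) assign(s, TRUE, envir = seen)
  n_excluded <- 0L
  n_dup <- 0L
  recs <- list()

  pend_dec <- list()
  pend_raw <- character(0)
  flush <- function() {
    if (!length(pend_dec)) return(invisible())
    canon <- canonical_smiles(pend_raw)
    for (j in seq_along(canon)) {
      smi <- canon[j]
      if (exists(smi, envir = seen, inherits = FALSE)) {
        if (smi %in% exclude) n_excluded <<- n_excluded + 1L
        else n_dup <<- n_dup + 1L
        next
      }
      assign(smi, TRUE, envir = seen)
      d <- pend_dec[[j]]
      recs[[length(recs) + 1L]] <<- data.frame(
        smiles = smi, scaffold_id = d$scaffold_id, n = d$n,
        assignment = as.character(jsonlite::toJSON(as.list(d$rgroups),
                                                   auto_unbox = TRUE)),
        stringsAsFactors = FALSE)
    }
    pend_dec <<- list()
    pend_raw <<- character(0)
    invisible()
  }
  push <- function(d) {
    pend_dec[[length(pend_dec) + 1L]] <<- d
    pend_raw <<- c(pend_raw, assemble_smiles(d))
    if (length(pend_dec) >= chunk_size) flush()
  }

  for (sc in rules$scaffolds) {
    for (n in rules$n_values) {
      for (block in r3_blocks(rules)) {
        open <- block$open
        grid_sizes <- rep(length(rules$swap_pool), length(open))
        n_assign <- prod(grid_sizes)
        for (r3f in block$frags) {
          for (gi in seq_len(n_assign)) {
            idx <- arrayInd(gi, .dim = grid_sizes)
            rg <- stats::setNames(rules$swap_pool[idx[1, ]], open)
            rg <- rg[rg != H_FRAG]
            rg[[block$key]] <- r3f
            if (identical(r3f, H_FRAG)) rg <- rg[names(rg) != "R3"]
            push(decomposition("pending", sc, n, rg))
          }
        }
      }
    }
  }
  flush()

  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(smiles = character(0), scaffold_id = character(0),
               n = integer(0), assignment = character(0))
  if (nrow(records)) {
    records <- cbind(id = sprintf("%s_%06d", id_prefix, seq_len(nrow(records))),
                     records, stringsAsFactors = FALSE)
  } else {
    records$id <- character(0)
  }

  if (validate && nrow(records)) {
    pyr <- smarts_count(records$smiles, "[n+]1ccccc1")
    oxi <- smarts_count(records$smiles, "[CX3]=[NX2][OX2H1]")
    bad <- which(is.na(pyr) | pyr != 1L | is.na(oxi) | oxi < 1L)
    if (length(bad)) {
      stop("enumeration produced ", length(bad), " structurally invalid ",
           "candidate(s), e.g. ", records$smiles[bad[1]], call. = FALSE)
    }
  }

  structure(list(
    records = records,
    stats = list(
      combinations = total,
      emitted = nrow(records),
      duplicates_removed = n_dup,
      inputs_excluded = n_excluded,
      per_scaffold = if (nrow(records)) table(records$scaffold_id) else table(character(0)),
      per_n = if (nrow(records)) table(records$n) else table(integer(0))
    )
  ), class = "candidate_library")
}

#' @export
print.candidate_library <- function(x, ...) {
  cat("<candidate_library> ", nrow(x$records), " candidates (",
      x$stats$combinations, " combinations, ",
      x$stats$duplicates_removed, " duplicates removed, ",
      x$stats$inputs_excluded, " inputs excluded)\n", sep = "")
  invisible(x)
}

#' Write a candidate library to disk
#'
#' Emits a (optionally gzip-compressed) `.smi` file of `smiles<TAB>id` lines
#' plus a JSON-lines provenance manifest (one record per candidate with
#' scaffold, linker length and assignment).
#'
#' @param library A `candidate_library`.
#' @param smi_path Output path; a `.gz` suffix triggers compression.
#' @param manifest_path Optional JSONL path (default `<smi_path>.jsonl`).
#' @return `smi_path`, invisibly.
#' @export
write_library <- function(library, smi_path,
                          manifest_path = paste0(smi_path, ".jsonl")) {
  stopifnot(inherits(library, "candidate_library"))
  con <- if (grepl("\\.gz$", smi_path)) gzfile(smi_path, "w") else
    file(smi_path, "w")
  writeLines(paste(library$records$smiles, library$records$id, sep = "\t"),
             con)
  close(con)
  man <- vapply(seq_len(nrow(library$records)), function(i) {
    r <- library$records[i, ]
    as.character(jsonlite::toJSON(list(
      id = r$id, smiles = r$smiles, scaffold_id = r$scaffold_id, n = r$n,
      assignment = jsonlite::fromJSON(r$assignment)), auto_unbox = TRUE))
  }, character(1))
  writeLines(man, manifest_path)
  invisible(smi_path)
}
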