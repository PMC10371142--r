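# SPPO scaffolds, R-group decomposition and reassembly.
#
# The SPPO chemotype is a pyridinium ring bearing an aldoxime (CH=N-OH),
# N-alkylated with a chain of n carbons ending in a phenoxy ether whose
# benzene ring carries substituents R1-R5. The three scaffolds shared by the
# tested compounds differ only in where the oxime sits on the pyridinium
# ring (ortho / meta / para to N+), so a scaffold id plus the linker length n
# plus a position -> fragment map determines a molecule completely.
#
# Position convention on the phenoxy ring: R3 is para to the ether oxygen
# (orientation-invariant), R1/R5 are the two ortho and R2/R4 the two meta
# positions. The ring's two mirror orientations only permute {R1,R5} and
# {R2,R4}; decomposition breaks the tie deterministically by taking the
# orientation whose (R1,...,R5) fragment tuple sorts first.
#
# Fragments are dummy-capped SMILES rooted at the attachment point ("*C" is
# methyl, "*OC" methoxy); hydrogen is the sentinel "H". "Special" fused-ring
# fragments carry two attachment points at adjacent positions (R2&R3 or
# R3&R4) and are written "*...*" with both dummies terminal, e.g. "*OCO*"
# for methylenedioxy.

SCAFFOLD_IDS <- c("pyr4", "pyr3", "pyr2")
POSITIONS <- paste0("R", 1:5)
SPECIAL_PAIRS <- c("R2&R3", "R3&R4")
H_FRAG <- "H"

#' The shared SPPO scaffolds
#'
#' @return Character vector of scaffold ids, in the fixed priority order used
#'   by [decompose()]: `"pyr4"` (oxime para to the ring nitrogen), `"pyr3"`
#'   (meta), `"pyr2"` (ortho).
#' @export
sppo_scaffolds <- function() SCAFFOLD_IDS

# ring-position (graph distance from N+ to the oxime-bearing ring carbon)
# -> scaffold id
scaffold_from_oxime_distance <- function(d) {
  switch(as.character(d), "1" = "pyr2", "2" = "pyr3", "3" = "pyr4",
         stop("oxime carbon at impossible ring distance ", d, call. = FALSE))
}

#' Construct a decomposition
#'
#' @param sppo_id Identifier of the source molecule (or a candidate id).
#' @param scaffold_id One of [sppo_scaffolds()].
#' @param n Linker length in carbons.
#' @param rgroups Named character vector of dummy-capped fragment SMILES.
#'   Names are positions `R1..R5` and/or the fused pairs `"R2&R3"`,
#'   `"R3&R4"`; every position must be covered exactly once; hydrogen is
#'   `"H"`. Unnamed positions default to hydrogen.
#' @return An object of class `sppo_decomposition`.
#' @export
decomposition <- function(sppo_id, scaffold_id, n, rgroups = character()) {
  scaffold_id <- match.arg(scaffold_id, SCAFFOLD_IDS)
  n <- as.integer(n)
  stopifnot(length(n) == 1L, n >= 1L)
  rgroups <- unlist(rgroups)
  if (is.null(names(rgroups)) && length(rgroups)) {
    stop("rgroups must be named by position", call. = FALSE)
  }
  bad <- setdiff(names(rgroups), c(POSITIONS, SPECIAL_PAIRS))
  if (length(bad)) stop("unknown position(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  covered <- if (length(rgroups))
    unlist(strsplit(names(rgroups), "&", fixed = TRUE)) else character(0)
  if (anyDuplicated(covered)) {
    stop("position(s) assigned more than once: ",
         paste(unique(covered[duplicated(covered)]), collapse = ", "),
         call. = FALSE)
  }
  for (p in setdiff(POSITIONS, covered)) rgroups[[p]] <- H_FRAG
  for (key in names(rgroups)) {
    frag <- rgroups[[key]]
    if (identical(frag, H_FRAG)) {
      if (key %in% SPECIAL_PAIRS) stop("a fused pair cannot be hydrogen",
                                       call. = FALSE)
      next
    }
    n_star <- lengths(regmatches(frag, gregexpr("*", frag, fixed = TRUE)))
    want <- if (key %in% SPECIAL_PAIRS) 2L else 1L
    if (n_star != want) {
      stop("fragment at ", key, " must carry ", want, " attachment point(s): ",
           frag, call. = FALSE)
    }
  }
  structure(list(sppo_id = as.character(sppo_id), scaffold_id = scaffold_id,
                 n = n, rgroups = rgroups[order(names(rgroups))]),
            class = "sppo_decomposition")
}

#' @export
print.sppo_decomposition <- function(x, ...) {
  subs <- x$rgroups[x$rgroups != H_FRAG]
  cat("<sppo_decomposition> ", x$sppo_id, ": scaffold ", x$scaffold_id,
      ", n=", x$n, if (length(subs)) paste0(", ",
        paste(names(subs), vapply(subs, identity, character(1)),
              sep = "=", collapse = " ")) else " (unsubstituted)",
      "\n", sep = "")
  invisible(x)
}

# ---- SMILES assembly ---------------------------------------------------

# rewrite every ring-closure token in a fragment SMILES to fresh two-digit
# %NN numbers so fragments never collide with scaffold ring numbers (1, 2)
# or with each other; `counter` is an environment holding the next number
remap_ring_closures <- function(s, counter) {
  chars <- strsplit(s, "")[[1]]
  out <- character(0)
  map <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (chars[j] != "]") j <- j + 1L
      out <- c(out, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == "%") {
      tok <- paste(chars[(i + 1L):(i + 2L)], collapse = "")
      if (is.null(map[[tok]])) {
        map[[tok]] <- sprintf("%%%d", counter$n)
        counter$n <- counter$n + 1L
      }
      out <- c(out, map[[tok]])
      i <- i + 3L
    } else if (grepl("[0-9]", ch)) {
      if (is.null(map[[ch]])) {
        map[[ch]] <- sprintf("%%%d", counter$n)
        counter$n <- counter$n + 1L
      }
      out <- c(out, map[[ch]])
      i <- i + 1L
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  paste(out, collapse = "")
}

# dummy-capped fragment -> inline SMILES body (attachment implicit at the
# preceding scaffold atom); fragment must be rooted at its dummy
frag_body <- function(frag, counter) {
  body <- sub("^\\[\\*\\]", "", sub("^\\*", "", frag))
  if (identical(body, frag)) {
    stop("fragment is not rooted at its attachment point: ", frag,
         call. = FALSE)
  }
  body <- sub("^-", "", body)
  remap_ring_closures(body, counter)
}

# two-dummy fragment "*...*" -> body with a ring-closure token appended to
# its last atom, for fused-ring attachment
special_frag_body <- function(frag, counter) {
  if (!grepl("^(\\[\\*\\]|\\*)", frag) || !grepl("(\\*|\\[\\*\\])$", frag)) {
    stop("fused-ring fragment must be a linear bridge written '*...*': ",
         frag, call. = FALSE)
  }
  body <- sub("(\\*|\\[\\*\\])$", "", sub("^(\\[\\*\\]|\\*)", "", frag))
  body <- sub("-$", "", sub("^-", "", body))
  if (!nzchar(body) || grepl("\\)$", body)) {
    stop("fused-ring fragment bridge must end on a plain atom: ", frag,
         call. = FALSE)
  }
  closure <- sprintf("%%%d", counter$n)
  counter$n <- counter$n + 1L
  list(body = remap_ring_closures(body, counter), closure = closure)
}

#' Reassemble molecules from decompositions
#'
#' Inverse of [decompose()]: builds the scaffold with an n-carbon linker and
#' attaches every fragment at its position, returning the canonical SMILES.
#' `reassemble(decompose(m))` is the identity on canonical SMILES for every
#' decomposable molecule.
#'
#' @param d An `sppo_decomposition`, or a list of them (canonicalized in one
#'   batch).
#' @return Canonical SMILES, one per decomposition.
#' @export
reassemble <- function(d) {
  if (!inherits(d, "sppo_decomposition")) {
    stopifnot(is.list(d), all(vapply(d, inherits, logical(1),
                                     "sppo_decomposition")))
    return(canonical_smiles(vapply(d, assemble_smiles, character(1))))
  }
  canonical_smiles(assemble_smiles(d))
}

# raw (non-canonical) template SMILES for a decomposition
assemble_smiles <- function(d) {
  stopifnot(inherits(d, "sppo_decomposition"))
  counter <- new.env(parent = emptyenv())
  counter$n <- 10L
  rg <- d$rgroups
  slot <- stats::setNames(rep("", 5L), POSITIONS)   # text appended to ring atom
  for (key in names(rg)) {
    frag <- rg[[key]]
    if (identical(frag, H_FRAG)) next
    if (key %in% SPECIAL_PAIRS) {
      pos <- strsplit(key, "&", fixed = TRUE)[[1]]
      sp <- special_frag_body(frag, counter)
      # the bridge hangs as a branch off the pair's first position (where
      # its root attachment point sits) and ring-closes onto the second
      slot[pos[1]] <- paste0("(", sp$body, sp$closure, ")")
      slot[pos[2]] <- sp$closure
    } else {
      slot[key] <- paste0("(", frag_body(frag, counter), ")")
    }
  }
  phenoxy <- paste0("Oc2c", slot["R1"], "c", slot["R2"], "c", slot["R3"],
                    "c", slot["R4"], "c2", sub("^\\((.*)\\)$", "\\1",
                                               slot["R5"]))
  linker <- paste0(strrep("C", d$n), phenoxy)
  switch(d$scaffold_id,
    pyr4 = paste0("ON=Cc1cc[n+](", linker, ")cc1"),
    pyr3 = paste0("ON=Cc1ccc[n+](", linker, ")c1"),
    pyr2 = paste0("ON=Cc1cccc[n+]1", linker)
  )
}

# ---- decomposition (graph walk) ----------------------------------------

# find the aromatic 6-ring through `center` (1-based atom index); returns
# the ring as an ordered atom-index cycle starting at `center`
find_aromatic_ring6 <- function(graph_aromatic, center) {
  vn <- igraph::V(graph_aromatic)$name
  cv <- which(vn == as.character(center))
  if (!length(cv)) return(NULL)
  nbs <- igraph::neighbors(graph_aromatic, cv)
  if (length(nbs) < 2L) return(NULL)
  combos <- utils::combn(seq_along(nbs), 2L)
  for (k in seq_len(ncol(combos))) {
    a <- nbs[combos[1L, k]]
    b <- nbs[combos[2L, k]]
    g2 <- igraph::delete_vertices(graph_aromatic, cv)
    an <- which(igraph::V(g2)$name == vn[a])
    bn <- which(igraph::V(g2)$name == vn[b])
    sp <- suppressWarnings(
      igraph::shortest_paths(g2, from = an, to = bn, output = "vpath")
    )$vpath[[1]]
    if (length(sp) == 5L) {
      return(as.integer(c(vn[cv], igraph::V(g2)$name[as.integer(sp)])))
    }
  }
  NULL
}

# phase 1 of decomposition: pure graph analysis, no backend calls; returns
# the scaffold id, linker length, bond cuts and the two ring orientations
decompose_analyze <- function(id, graph) {
  atoms <- graph$atoms
  bonds <- graph$bonds
  fail <- function(...) stop("cannot decompose ", id, ": ", ..., call. = FALSE)

  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(bonds$a), to = as.character(bonds$b)),
    directed = FALSE,
    vertices = data.frame(name = as.character(atoms$index))
  )
  arom <- igraph::subgraph_from_edges(
    g, igraph::E(g)[which(bonds$aromatic)], delete.vertices = FALSE
  )
  nbrs <- function(i) as.integer(igraph::V(g)$name[
    igraph::neighbors(g, which(igraph::V(g)$name == as.character(i)))])

  # pyridinium nitrogen
  npos <- atoms$index[atoms$symbol == "N" & atoms$charge == 1L & atoms$aromatic]
  if (length(npos) != 1L) fail("expected exactly one pyridinium nitrogen, ",
                               "found ", length(npos))
  pyr_ring <- find_aromatic_ring6(arom, npos)
  if (is.null(pyr_ring)) fail("pyridinium nitrogen is not in an aromatic ",
                              "6-ring")
  ring_sym <- atoms$symbol[match(pyr_ring, atoms$index)]
  if (!all(ring_sym[-1] == "C")) fail("pyridinium ring is not C5N")

  # the oxime carbon hanging off the ring: ring C - C(=N-OH)
  bond_between <- function(i, j) {
    hit <- (bonds$a == i & bonds$b == j) | (bonds$a == j & bonds$b == i)
    bonds[hit, , drop = FALSE]
  }
  oxime_ring_atom <- NA_integer_
  for (rc in pyr_ring[-1]) {
    for (x in setdiff(nbrs(rc), pyr_ring)) {
      if (atoms$symbol[x] != "C" || atoms$aromatic[x]) next
      for (y in setdiff(nbrs(x), rc)) {
        if (atoms$symbol[y] != "N") next
        if (bond_between(x, y)$order != 2) next
        os <- setdiff(nbrs(y), x)
        if (length(os) == 1L && atoms$symbol[os] == "O" &&
            atoms$degree[os] == 1L && atoms$n_h[os] >= 1L) {
          if (!is.na(oxime_ring_atom)) fail("multiple oximes on the ",
                                            "pyridinium ring")
          oxime_ring_atom <- rc
        }
      }
    }
  }
  if (is.na(oxime_ring_atom)) fail("no oxime substituent on the pyridinium ",
                                   "ring")
  ring_pos <- match(oxime_ring_atom, pyr_ring)  # 1 = N+, 2..6 around the ring
  dist_n <- min(ring_pos - 1L, 7L - ring_pos)
  scaffold_id <- scaffold_from_oxime_distance(dist_n)

  # every other pyridinium carbon must be bare (scaffold contract)
  for (rc in setdiff(pyr_ring[-1], oxime_ring_atom)) {
    if (length(setdiff(nbrs(rc), pyr_ring))) {
      fail("pyridinium ring carries substituents beyond the oxime")
    }
  }

  # alkyl linker from N+ to the ether oxygen
  start <- setdiff(nbrs(npos), pyr_ring)
  if (length(start) != 1L) fail("pyridinium nitrogen must carry exactly one ",
                                "exocyclic substituent (the linker)")
  chain <- integer(0)
  prev <- npos
  cur <- start
  repeat {
    if (atoms$symbol[cur] == "O") break
    if (atoms$symbol[cur] != "C" || atoms$aromatic[cur]) {
      fail("linker is not a plain alkyl chain")
    }
    nxt <- setdiff(nbrs(cur), prev)
    if (length(nxt) != 1L) fail("branched or truncated linker")
    chain <- c(chain, cur)
    prev <- cur
    cur <- nxt
  }
  n <- length(chain)
  ether_o <- cur
  ipso <- setdiff(nbrs(ether_o), prev)
  if (length(ipso) != 1L || !atoms$aromatic[ipso]) {
    fail("linker oxygen is not an aryl ether")
  }

  # phenoxy ring and its substituents
  ph_ring <- find_aromatic_ring6(arom, ipso)
  if (is.null(ph_ring) ||
      !all(atoms$symbol[match(ph_ring, atoms$index)] == "C")) {
    fail("no benzene ring on the ether oxygen")
  }
  # ph_ring = ipso, nb1, path..., nb2; reorder to a walk around the cycle
  ring_cycle <- ph_ring
  # substituent components: everything left when the ring is deleted
  g_cut <- igraph::delete_vertices(
    g, which(igraph::V(g)$name %in% as.character(ring_cycle)))
  comps <- igraph::components(g_cut)
  comp_of <- stats::setNames(comps$membership, igraph::V(g_cut)$name)
  attach_list <- list()  # component id -> list(ring atoms, frag atoms)
  for (rc in ring_cycle) {
    for (x in setdiff(nbrs(rc), ring_cycle)) {
      cid <- as.character(comp_of[[as.character(x)]])
      if (is.null(attach_list[[cid]])) {
        attach_list[[cid]] <- list(ring = integer(0), frag = integer(0))
      }
      attach_list[[cid]]$ring <- c(attach_list[[cid]]$ring, rc)
      attach_list[[cid]]$frag <- c(attach_list[[cid]]$frag, x)
    }
  }
  # the linker side attaches at ipso through the ether oxygen
  linker_cid <- as.character(comp_of[[as.character(ether_o)]])
  if (!identical(attach_list[[linker_cid]]$ring, as.integer(ipso))) {
    fail("phenoxy ring carries the linker at more than one position")
  }
  attach_list[[linker_cid]] <- NULL

  # ring positions in the two orientations (R1..R5 away from ipso)
  ordered <- ring_cycle[c(1L, 2L, 3L, 4L, 5L, 6L)]
  # ring_cycle from find_aromatic_ring6 is already an ordered cycle
  orientations <- list(ordered[-1L], rev(ordered[-1L]))

  cuts <- list()
  cut_pos <- list()  # per cut: the ring atom it came from
  for (cid in names(attach_list)) {
    at <- attach_list[[cid]]
    if (length(at$ring) > 2L) fail("substituent bridges more than two ring ",
                                   "positions")
    for (j in seq_along(at$ring)) {
      cuts[[length(cuts) + 1L]] <- c(at$ring[j], at$frag[j])
      cut_pos[[length(cut_pos) + 1L]] <- at$ring[j]
    }
  }

  list(id = id, scaffold_id = scaffold_id, n = n, cuts = cuts,
       cut_pos = cut_pos, orientations = orientations)
}

# phase 2: position the extracted fragments and break the orientation tie
decompose_finalize <- function(an, frag_res) {
  fail <- function(...) stop("cannot decompose ", an$id, ": ", ...,
                             call. = FALSE)
  cuts <- an$cuts
  cut_pos <- an$cut_pos
  frag_by_cut <- list()
  if (length(cuts)) {
    if (!is.null(frag_res$error)) fail("fragment extraction: ",
                                       frag_res$error)
    for (fr in frag_res$fragments) {
      if (fr$n_dummies == 0L) next
      # the core-side fragment contains the aromatic pyridinium nitrogen
      if (grepl("[n+]", fr$canonical, fixed = TRUE)) next
      for (ci in unlist(fr$cut_ids)) frag_by_cut[[as.character(ci)]] <- fr
    }
  }
  rooted_at_cut <- function(fr, cut_id) {
    for (r in fr$rooted) if (r$cut_id == cut_id) return(r$smiles)
    fail("internal: no rooted form for cut ", cut_id)
  }

  build_assignment <- function(order) {
    rg <- character(0)
    canon_by_pos <- stats::setNames(rep(H_FRAG, 5L), POSITIONS)
    done <- integer(0)
    for (ci in seq_along(cuts)) {
      if (ci %in% done) next
      fr <- frag_by_cut[[as.character(ci)]]
      if (is.null(fr)) fail("internal: missing fragment for a cut")
      if (fr$n_dummies == 2L) {
        ids <- sort(unlist(fr$cut_ids))
        done <- c(done, ids)
        ring_ats <- vapply(ids, function(k) cut_pos[[k]], numeric(1))
        pos_idx <- match(ring_ats, order)
        ord2 <- order(pos_idx)
        pair <- paste0("R", pos_idx[ord2][1], "&R", pos_idx[ord2][2])
        if (!pair %in% SPECIAL_PAIRS) {
          fail("fused substituent at unsupported positions ", pair)
        }
        # root the bridge at the attachment sitting on the pair's first
        # position, so reassembly rebuilds the same direction
        rg[[pair]] <- rooted_at_cut(fr, ids[ord2][1])
        canon_by_pos[pos_idx] <- fr$canonical
      } else {
        done <- c(done, ci)
        p <- paste0("R", match(cut_pos[[ci]], order))
        rg[[p]] <- fr$smiles
        canon_by_pos[[p]] <- fr$canonical
      }
    }
    list(rg = rg, key = paste(canon_by_pos, collapse = "\r"))
  }

  pick <- NULL
  for (ord in an$orientations) {
    cand <- tryCatch(build_assignment(ord), error = function(e) NULL)
    if (is.null(cand)) next
    if (is.null(pick) || cand$key < pick$key) pick <- cand
  }
  if (is.null(pick)) fail("could not assign substituent positions")

  decomposition(an$id, an$scaffold_id, an$n, pick$rg)
}

#' Decompose SPPO molecules into scaffold, linker length and R-groups
#'
#' Walks the molecular graph: locates the pyridinium nitrogen and its
#' aromatic ring, identifies the ring position of the aldoxime (which fixes
#' the scaffold), measures the alkyl linker to the ether oxygen, and factors
#' the phenoxy ring's substituents into positioned, dummy-capped fragments.
#' Substituents spanning two adjacent positions (fused rings) are returned
#' under the pair keys `"R2&R3"` / `"R3&R4"`.
#'
#' @param compounds A compound `data.frame` ([compound_records()]) or a
#'   character vector of SMILES.
#' @return A list of `sppo_decomposition` objects, one per molecule (errors
#'   name the offending id). For a single SMILES, the bare decomposition.
#' @export
decompose <- function(compounds) {
  single <- FALSE
  if (is.character(compounds)) {
    single <- length(compounds) == 1L
    compounds <- compound_records(paste0("m", seq_along(compounds)),
                                  compounds, role = "SPPO")
  }
  graphs <- mol_graphs(compounds$smiles)
  analyses <- vector("list", nrow(compounds))
  for (i in seq_len(nrow(compounds))) {
    if (is.null(graphs[[i]])) {
      stop("cannot decompose ", compounds$id[i], ": unparseable SMILES",
           call. = FALSE)
    }
    analyses[[i]] <- decompose_analyze(compounds$id[i], graphs[[i]])
  }
  # one backend batch extracts the fragments of every molecule that has cuts
  with_cuts <- which(vapply(analyses, function(a) length(a$cuts) > 0,
                            logical(1)))
  frag_res <- vector("list", nrow(compounds))
  if (length(with_cuts)) {
    jobs <- lapply(with_cuts, function(i) {
      list(smiles = compounds$smiles[i], cuts = analyses[[i]]$cuts)
    })
    frag_res[with_cuts] <- cut_fragments(jobs)
  }
  out <- vector("list", nrow(compounds))
  for (i in seq_len(nrow(compounds))) {
    out[[i]] <- decompose_finalize(analyses[[i]], frag_res[[i]])
    if (!(out[[i]]$n %in% 3:5)) attr(out[[i]], "out_of_rule") <- TRUE
  }
  names(out) <- compounds$id
  if (single) out[[1]] else out
}

#' Pool R-group fragments from a set of decompositions
#'
#' @param decs List of `sppo_decomposition` objects.
#' @return A `data.frame` with one row per unique fragment: `smiles`,
#'   `positions_observed` (comma-joined), `n_attachments`, `source_ids`.
#' @export
fragment_pool <- function(decs) {
  if (inherits(decs, "sppo_decomposition")) decs <- list(decs)
  rows <- list()
  for (d in decs) {
    for (key in names(d$rgroups)) {
      frag <- d$rgroups[[key]]
      rows[[length(rows) + 1L]] <- data.frame(
        smiles = frag, position = key, source_id = d$sppo_id,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  agg <- lapply(split(df, df$smiles), function(s) {
    data.frame(
      smiles = s$smiles[1],
      positions_observed = paste(sort(unique(s$position)), collapse = ","),
      n_attachments = if (s$smiles[1] == H_FRAG) 1L else
        lengths(regmatches(s$smiles[1],
                           gregexpr("*", s$smiles[1], fixed = TRUE))),
      source_ids = paste(sort(unique(s$source_id)), collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$smiles), , drop = FALSE]
}
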