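# Single entry point to the batched RDKit helper. Every chemistry primitive
# (canonical SMILES, the descriptor battery, SMARTS counts, molecule graphs,
# bond-cut fragment extraction) funnels through here so one Python start-up
# is paid per *batch*, never per molecule.

the <- new.env(parent = emptyenv())

#' Locate the Python interpreter used for chemistry primitives
#'
#' The package delegates low-level cheminformatics (SMILES parsing and
#' canonicalization, the 2D descriptor battery, SMARTS matching, molecular
#' graphs) to RDKit through a small batched helper script. The interpreter is
#' taken from `options(oximescreen.python = ...)`, then the
#' `OXIMESCREEN_PYTHON` environment variable, then `python` on the PATH.
#'
#' @return Path to the Python executable.
#' @export
chem_python <- function() {
  py <- getOption("oximescreen.python", "")
  if (!nzchar(py)) py <- Sys.getenv("OXIMESCREEN_PYTHON", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) {
    stop("no Python interpreter found; set options(oximescreen.python=) ",
         "or put `python` (with RDKit) on the PATH", call. = FALSE)
  }
  py
}

backend_script <- function() {
  path <- system.file("python", "chem_backend.py", package = "oximescreen")
  if (!nzchar(path)) {
    stop("chem_backend.py not found in the installed package", call. = FALSE)
  }
  path
}

chem_call <- function(cmd, payload = list()) {
  payload$cmd <- cmd
  req <- tempfile(fileext = ".json")
  on.exit(unlink(req), add = TRUE)
  jsonlite::write_json(payload, req, auto_unbox = TRUE, digits = NA,
                       null = "null")
  out <- suppressWarnings(
    system2(chem_python(), shQuote(backend_script()),
            stdout = TRUE, stderr = TRUE, stdin = req)
  )
  status <- attr(out, "status")
  txt <- paste(out, collapse = "\n")
  res <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e) NULL)
  if (!is.null(status) && status != 0L || is.null(res)) {
    stop("chemistry backend failed (cmd=", cmd, "): ", txt, call. = FALSE)
  }
  if (!isTRUE(res$ok)) {
    stop("chemistry backend error (cmd=", cmd, "): ", res$error, call. = FALSE)
  }
  res
}

#' Version of the chemistry toolkit behind the backend
#'
#' @return A string such as `"2024.09.2"`; recorded in run manifests so
#'   descriptor batteries are pinned to the toolkit that produced them.
#' @export
chem_toolkit_version <- function() {
  if (is.null(the$rdkit_version)) {
    the$rdkit_version <- chem_call("version")$rdkit_version
  }
  the$rdkit_version
}

#' Canonicalize SMILES strings
#'
#' @param smiles Character vector of SMILES.
#' @param strict If `TRUE` (default) any unparseable entry is an error naming
#'   the offending positions; if `FALSE`, failures come back as `NA`.
#' @return Character vector of canonical SMILES, same length as the input.
#'   Canonicalization is idempotent: `canonical_smiles(canonical_smiles(s))`
#'   equals `canonical_smiles(s)`.
#' @examples
#' \dontrun{canonical_smiles(c("OCC", "CCO"))  # both "CCO"}
#' @export
canonical_smiles <- function(smiles, strict = TRUE) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  if (is.null(the$canon_cache)) the$canon_cache <- new.env(parent = emptyenv())
  cache <- the$canon_cache
  out <- rep(NA_character_, length(smiles))
  key <- paste0("s:", smiles)
  hit <- vapply(key, exists, logical(1), envir = cache, inherits = FALSE)
  hit[is.na(smiles)] <- FALSE
  out[hit] <- vapply(key[hit], get, character(1), envir = cache,
                     inherits = FALSE)
  todo <- which(!hit & !is.na(smiles))
  if (length(todo)) {
    res <- chem_call("canon", list(smiles = as.list(unname(smiles[todo]))))
    vals <- vapply(res$canonical, function(x) {
      if (is.null(x)) NA_character_ else x
    }, character(1))
    out[todo] <- vals
    ok <- !is.na(vals)
    for (j in which(ok)) assign(key[todo[j]], vals[j], envir = cache)
  }
  if (strict && anyNA(out)) {
    bad <- which(is.na(out))
    stop("unparseable SMILES at position(s) ",
         paste(utils::head(bad, 10), collapse = ", "), ": ",
         paste(utils::head(smiles[bad], 10), collapse = ", "), call. = FALSE)
  }
  out
}

#' Count SMARTS pattern matches
#'
#' @param smiles Character vector of SMILES.
#' @param smarts A single SMARTS pattern.
#' @return Integer vector of (unique) match counts; `NA` for unparseable
#'   molecules.
#' @export
smarts_count <- function(smiles, smarts) {
  stopifnot(is.character(smiles), is.character(smarts), length(smarts) == 1L)
  if (length(smiles) == 0L) return(integer(0))
  res <- chem_call("substruct_count",
                   list(smiles = as.list(unname(smiles)), smarts = smarts))
  vapply(res$counts, function(x) if (is.null(x)) NA_integer_ else
    as.integer(x), integer(1))
}

# atom/bond tables for the decomposition graph walk
mol_graphs <- function(smiles) {
  res <- chem_call("graphs", list(smiles = as.list(unname(smiles))))
  lapply(res$mols, function(m) {
    if (is.null(m)) return(NULL)
    atoms <- do.call(rbind, lapply(m$atoms, function(a) {
      data.frame(index = a$index, symbol = a$symbol, charge = a$charge,
                 aromatic = a$aromatic, in_ring = a$in_ring, n_h = a$n_h,
                 degree = a$degree, stringsAsFactors = FALSE)
    }))
    bonds <- if (length(m$bonds)) {
      do.call(rbind, lapply(m$bonds, function(b) {
        data.frame(a = b$a, b = b$b, order = b$order, aromatic = b$aromatic)
      }))
    } else {
      data.frame(a = integer(0), b = integer(0), order = numeric(0),
                 aromatic = logical(0))
    }
    list(atoms = atoms, bonds = bonds)
  })
}

# cut the listed bonds (core_atom, fragment_atom) and return the dummy-capped
# fragments; see inst/python/chem_backend.py for the contract
cut_fragments <- function(jobs) {
  res <- chem_call("cut_fragments", list(jobs = lapply(jobs, function(j) {
    list(smiles = j$smiles, cuts = lapply(j$cuts, as.list))
  })))
  res$results
}
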