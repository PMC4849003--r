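# structure_io: PDB reading/writing, the complex3d container and partner
# handling. Low-level record parsing and column-exact writing are delegated
# to bio3d; this layer adds the model-building policy (altloc resolution,
# heteroatom side store, MSE->MET) and validation.

#' Read a protein complex from a PDB file
#'
#' Parses ATOM/HETATM records into a \code{complex3d} object. The protein
#' model keeps author chain identifiers, residue numbering and insertion
#' codes. Policy applied while building the model:
#' \itemize{
#'   \item alternate locations are resolved to the highest-occupancy
#'     conformer (ties broken by altloc letter order);
#'   \item HETATM records and waters are excluded from the protein model but
#'     retained in a side store (\code{$het});
#'   \item selenomethionine (MSE) is renamed to MET; other non-standard
#'     residues are moved to the side store;
#'   \item for multi-model (NMR) files only the first model is kept;
#'   \item duplicate atom names within a residue raise a warning and the
#'     first occurrence is kept.
#' }
#'
#' @param source path to a PDB file, or a character vector of PDB-format
#'   lines.
#' @return A \code{complex3d} object: list with \code{atoms} (data frame with
#'   columns chain, resno, insert, resname, atom, element, x, y, z) and
#'   \code{het} (excluded records in the same layout).
#' @examples
#' pdb <- make_synthetic_complex(chain_lengths = c(4, 4), separation = 20)
#' f <- tempfile(fileext = ".pdb")
#' write_pdb(pdb, f)
#' cx <- read_pdb(f)
#' chain_ids(cx)
#' @export
read_pdb <- function(source) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    path <- source
  } else {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(unlist(strsplit(paste(source, collapse = "\n"), "\n")), path)
  }
  raw <- readLines(path, warn = FALSE)
  if (!any(grepl("^ATOM  ", raw))) {
    bad <- which(!grepl("^(ATOM  |HETATM|TER|END|MODEL|ENDMDL|REMARK|HEADER|TITLE|COMPND|SEQRES|CRYST1|SCALE|ORIGX|ANISOU|CONECT|MASTER|EXPDTA|AUTHOR|REVDAT|JRNL|DBREF|SEQADV|HET |HETNAM|FORMUL|HELIX|SHEET|SSBOND|LINK|SITE|\\s*$)", raw))
    first_bad <- if (length(bad)) sprintf(" (first offending line %d: %s)",
                                          bad[1], substr(raw[bad[1]], 1, 40)) else ""
    stop("no ATOM records found in PDB input", first_bad)
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom

  # first model only: bio3d already collapses to model 1 with multi = FALSE

  # altloc resolution: per (chain, resno, insert, atom name) keep the
  # highest-occupancy conformer, ties broken by altloc letter order
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "|")
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, ]
  dup <- duplicated(paste(at$chain, at$resno, at$insert, at$resid, at$elety,
                          sep = "|"))
  if (any(dup & at$alt == "")) {
    warning("duplicate atom name(s) within a residue; keeping first occurrence")
  }
  at <- at[!dup, ]
  at <- at[order(at$eleno), ]   # restore file order after dedup

  at$resid <- toupper(at$resid)
  at$resid[at$resid == "MSE"] <- "MET"
  at$elety[at$elety == "SE" & at$resid == "MET"] <- "SD"

  is_water <- at$resid %in% c("HOH", "WAT", "DOD")
  is_protein <- at$type == "ATOM" & at$resid %in% AA3 & !is_water
  # HETATM-coded MSE ends up as MET but arrived as HETATM; admit it
  is_protein <- is_protein | (at$resid == "MET" & at$type == "HETATM")

  mk <- function(d) {
    data.frame(chain = d$chain, resno = d$resno, insert = d$insert,
               resname = d$resid, atom = d$elety,
               element = element_of(d$elety, d$elesy),
               x = d$x, y = d$y, z = d$z, stringsAsFactors = FALSE)
  }
  atoms <- mk(at[is_protein, , drop = FALSE])
  het <- mk(at[!is_protein, , drop = FALSE])
  if (nrow(atoms) == 0) stop("no standard amino-acid ATOM records in input")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in PDB input")
  }
  # hydrogens are not part of the heavy-atom model
  atoms <- atoms[atoms$element != "H", , drop = FALSE]
  new_complex3d(atoms, het)
}

#' @noRd
new_complex3d <- function(atoms, het = NULL) {
  rownames(atoms) <- NULL
  if (is.null(het)) {
    het <- atoms[0, , drop = FALSE]
  }
  structure(list(atoms = atoms, het = het), class = "complex3d")
}

#' @export
print.complex3d <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("<complex3d> %d chain(s), %d residue(s), %d heavy atom(s)\n",
              length(unique(x$atoms$chain)), nrow(rt), nrow(x$atoms)))
  for (ch in unique(rt$chain)) {
    cat(sprintf("  chain %s: %d residues\n", ch, sum(rt$chain == ch)))
  }
  if (nrow(x$het)) cat(sprintf("  (+%d heteroatom/water records in side store)\n",
                               nrow(x$het)))
  invisible(x)
}

#' Chain identifiers of a complex
#' @param complex a \code{complex3d} object.
#' @return character vector of chain identifiers in file order.
#' @export
chain_ids <- function(complex) unique(complex$atoms$chain)

#' Residue inventory of a complex
#'
#' @param complex a \code{complex3d} object.
#' @return data frame with one row per residue: chain, resno, insert, resname,
#'   in atom order.
#' @export
residue_table <- function(complex) {
  a <- complex$atoms
  key <- paste(a$chain, a$resno, a$insert, sep = "|")
  keep <- !duplicated(key)
  out <- a[keep, c("chain", "resno", "insert", "resname")]
  rownames(out) <- NULL
  out
}

#' @noRd
coords_matrix <- function(complex) {
  as.matrix(complex$atoms[, c("x", "y", "z")])
}

#' @noRd
set_coords <- function(complex, xyz) {
  complex$atoms$x <- xyz[, 1]
  complex$atoms$y <- xyz[, 2]
  complex$atoms$z <- xyz[, 3]
  complex
}

#' @noRd
validate_complex <- function(complex) {
  a <- complex$atoms
  if (!nrow(a)) stop("complex has no atoms")
  rk <- paste(a$chain, a$resno, a$insert, sep = "|")
  # residue key must not recur after an intervening different residue
  runs <- rle(rk)$values
  if (anyDuplicated(runs)) stop("(chain, residue number, insertion code) not unique within the complex")
  if (any(!is.finite(as.matrix(a[, c("x", "y", "z")])))) {
    stop("non-finite coordinates")
  }
  invisible(complex)
}

#' Write a complex to a PDB file
#'
#' Emits standard fixed-column ATOM records (coordinates with 3 decimals) with
#' a TER record after each chain. A round trip through \code{read_pdb}
#' reproduces chains, residue numbering and coordinates to PDB precision.
#'
#' @param complex a \code{complex3d} object.
#' @param destination output file path.
#' @return invisibly, the destination path.
#' @export
write_pdb <- function(complex, destination) {
  a <- complex$atoms
  dir <- dirname(destination)
  if (!dir.exists(dir)) stop("unwritable destination: directory does not exist: ", dir)
  lines <- character(0)
  serial <- 0L
  for (ch in unique(a$chain)) {
    d <- a[a$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      serial <- serial + 1L
      nm <- d$atom[i]
      # PDB atom-name column convention: element right-aligned in cols 13-14
      nm_fmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
      lines <- c(lines, sprintf(
        "ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial %% 100000L, nm_fmt, d$resname[i], ch, d$resno[i],
        ifelse(d$insert[i] == "", " ", d$insert[i]),
        d$x[i], d$y[i], d$z[i], 1, 0, d$element[i]))
    }
    serial <- serial + 1L
    lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d",
                              serial %% 100000L,
                              d$resname[nrow(d)], ch, d$resno[nrow(d)]))
  }
  lines <- c(lines, "END")
  con <- tryCatch(file(destination, "w"),
                  error = function(e) stop("unwritable destination: ", destination))
  on.exit(close(con), add = TRUE)
  writeLines(lines, con)
  invisible(destination)
}

#' Define the two binding partners of a complex
#'
#' @param partner1,partner2 character vectors of chain identifiers; must be
#'   non-empty and disjoint.
#' @return object of class \code{partner_definition}.
#' @examples
#' partner_definition("A", "B")
#' @export
partner_definition <- function(partner1, partner2) {
  partner1 <- unique(as.character(partner1))
  partner2 <- unique(as.character(partner2))
  if (!length(partner1) || !length(partner2)) {
    stop("both partners must name at least one chain")
  }
  if (length(intersect(partner1, partner2))) {
    stop("partner chain sets overlap: ",
         paste(intersect(partner1, partner2), collapse = ", "))
  }
  structure(list(partner1 = partner1, partner2 = partner2),
            class = "partner_definition")
}

#' Split a complex into its two binding partners
#'
#' Rigid split: each partner keeps its chains at the complex-frame
#' coordinates (no re-minimization), as required by the single-trajectory
#' binding convention.
#'
#' @param complex a \code{complex3d} object.
#' @param partners a \code{\link{partner_definition}}.
#' @return list with elements \code{partner1} and \code{partner2}, each a
#'   \code{complex3d}. Chains belonging to neither partner are dropped with a
#'   warning.
#' @export
split_partners <- function(complex, partners) {
  stopifnot(inherits(partners, "partner_definition"))
  present <- chain_ids(complex)
  named <- c(partners$partner1, partners$partner2)
  missing <- setdiff(named, present)
  if (length(missing)) {
    stop("partner chain(s) not present in complex: ",
         paste(missing, collapse = ", "))
  }
  excluded <- setdiff(present, named)
  if (length(excluded)) {
    warning("chain(s) in neither partner excluded from the binding reaction: ",
            paste(excluded, collapse = ", "))
  }
  sub <- function(chains) {
    new_complex3d(complex$atoms[complex$atoms$chain %in% chains, , drop = FALSE],
                  complex$het[0, , drop = FALSE])
  }
  list(partner1 = sub(partners$partner1), partner2 = sub(partners$partner2))
}

#' Specify a point mutation
#'
#' @param chain chain identifier.
#' @param position author residue number.
#' @param wt one-letter code of the wild-type residue (checked against the
#'   structure when the mutation is applied).
#' @param mt one-letter code of the mutant residue.
#' @param insert insertion code (default "").
#' @return object of class \code{mutation_spec}.
#' @examples
#' mutation_spec("A", 41, "K", "E")
#' parse_mutation("A:41:K>E")
#' @export
mutation_spec <- function(chain, position, wt, mt, insert = "") {
  wt <- toupper(wt); mt <- toupper(mt)
  if (!(wt %in% AA1) || !(mt %in% AA1)) {
    stop("residue codes must be standard one-letter amino acids; got ",
         wt, " -> ", mt)
  }
  structure(list(chain = as.character(chain), position = as.integer(position),
                 wt = wt, mt = mt, insert = insert),
            class = "mutation_spec")
}

#' @rdname mutation_spec
#' @param token mutation token in \code{CHAIN:POS:WT>MT} form, e.g.
#'   \code{"A:41:K>E"}.
#' @export
parse_mutation <- function(token) {
  m <- regmatches(token, regexec("^([A-Za-z0-9]):([0-9]+)([A-Za-z]?):([A-Z])>([A-Z])$",
                                 token))[[1]]
  if (!length(m)) stop("malformed mutation token (expected CHAIN:POS:WT>MT): ",
                       token)
  mutation_spec(m[2], as.integer(m[3]), m[5], m[6], insert = m[4])
}

#' @export
format.mutation_spec <- function(x, ...) {
  sprintf("%s:%d%s:%s>%s", x$chain, x$position, x$insert, x$wt, x$mt)
}

#' @export
print.mutation_spec <- function(x, ...) {
  cat("<mutation>", format(x), "\n")
  invisible(x)
}

#' @noRd
residue_index <- function(complex, chain, position, insert = "") {
  a <- complex$atoms
  which(a$chain == chain & a$resno == position & a$insert == insert)
}
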