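#' Construct a topology
#'
#' A topology holds the per-atom metadata every analysis relies on: names,
#' residues, masses, partial charges, Lennard-Jones parameters,
#' hydrogen-bond donor/acceptor flags, plus the index triplets of rigid
#' three-site waters and named atom groups. Atom indices are 1-based;
#' residue ids keep the 1-based convention of PDB/GRO files.
#'
#' @param atoms A data.frame with columns `name`, `element`, `resid`,
#'   `resname` and optionally `mass` (amu), `charge` (e), `eps` (kJ/mol),
#'   `sigma` (nm), `is_donor`, `is_acceptor`. Missing numeric columns are
#'   initialised to `NA`; flags to `FALSE`.
#' @param waters Integer matrix with 3 columns (O, H1, H2 atom indices) or
#'   `NULL` to auto-detect with [find_waters()].
#' @param groups Named list of integer atom-index vectors.
#' @param donor_hydrogens Named list mapping donor atom index (as character)
#'   to the indices of its attached hydrogens.
#' @return An object of class `cw_topology`.
#' @export
topology <- function(atoms, waters = NULL, groups = list(),
                     donor_hydrogens = list()) {
  req <- c("name", "element", "resid", "resname")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  n <- nrow(atoms)
  for (col in c("mass", "charge", "eps", "sigma"))
    if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  for (col in c("is_donor", "is_acceptor"))
    if (is.null(atoms[[col]])) atoms[[col]] <- FALSE
  atoms$index <- seq_len(n)
  if (is.null(waters)) waters <- find_waters(atoms)
  waters <- validate_waters(waters, n)
  if (!all(vapply(groups, function(g) all(g >= 1 & g <= n), logical(1))))
    stop("group indices out of range")
  structure(list(atoms = atoms, waters = waters, groups = groups,
                 donor_hydrogens = donor_hydrogens),
            class = "cw_topology")
}

validate_waters <- function(waters, n_atoms) {
  if (is.null(waters) || nrow(waters) == 0L)
    return(matrix(integer(0), 0, 3, dimnames = list(NULL, c("O", "H1", "H2"))))
  waters <- matrix(as.integer(waters), ncol = 3)
  colnames(waters) <- c("O", "H1", "H2")
  idx <- as.vector(waters)
  if (any(idx < 1L | idx > n_atoms)) stop("water triplet index out of range")
  if (anyDuplicated(idx)) stop("water triplets are not disjoint")
  waters
}

#' @export
print.cw_topology <- function(x, ...) {
  cat(sprintf("<cw_topology> %d atoms, %d residues, %d waters, %d groups\n",
              nrow(x$atoms), length(unique(paste(x$atoms$resid, x$atoms$resname))),
              nrow(x$waters), length(x$groups)))
  invisible(x)
}

#' @export
length.cw_topology <- function(x) nrow(x$atoms)

# Residue names recognised as water and the O/H atom-name patterns.
water_name_rules <- function() {
  list(resnames = c("SOL", "TIP3", "HOH", "WAT"),
       o_names  = c("OW", "O", "OH2"),
       h_names  = c("HW1", "HW2", "H1", "H2"))
}

#' Detect rigid three-site waters from residue and atom names
#'
#' Residues named SOL/TIP3/HOH/WAT whose atoms match the conventional
#' O/H naming (OW|O|OH2 and HW1|HW2|H1|H2) are collected into disjoint
#' (O, H1, H2) triplets.
#'
#' @param atoms Atom data.frame as in [topology()].
#' @param rules Optional override of the naming rules (a list with
#'   `resnames`, `o_names`, `h_names`).
#' @return Integer matrix with columns O, H1, H2 (possibly 0 rows).
#' @export
find_waters <- function(atoms, rules = water_name_rules()) {
  is_w <- atoms$resname %in% rules$resnames
  if (!any(is_w))
    return(matrix(integer(0), 0, 3, dimnames = list(NULL, c("O", "H1", "H2"))))
  idx <- which(is_w)
  key <- paste(atoms$resid[idx], atoms$resname[idx])
  trips <- lapply(split(idx, key), function(ii) {
    o <- ii[atoms$name[ii] %in% rules$o_names]
    h <- ii[atoms$name[ii] %in% rules$h_names]
    if (length(o) != 1L || length(h) != 2L)
      stop("water residue ", key[match(ii[1], idx)],
           " does not have one O and two H atoms")
    c(o, sort(h))
  })
  out <- do.call(rbind, trips[order(vapply(trips, `[`, integer(1), 1L))])
  colnames(out) <- c("O", "H1", "H2")
  out
}

#' Select atoms by a small query language
#'
#' Supported grammar: `resname NAME`, `resid N`, `resid N:M` (range),
#' `name NAME`, `element E`, the keyword `water`, parentheses and the
#' boolean operators `and`, `or`, `not`. Matching is case-sensitive on
#' names. A combined form like `"resid 406 and resname VAL"` selects the
#' atoms of residue VAL406. The result preserves atom order and an
#' unmatched selection returns an empty set (not an error).
#'
#' @param top A `cw_topology`.
#' @param expression Selection string.
#' @return Sorted integer vector of 1-based atom indices.
#' @export
select_atoms <- function(top, expression) {
  stopifnot(inherits(top, "cw_topology"))
  toks <- sel_tokenize(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L; st$src <- expression
  mask <- sel_parse_or(st, top)
  if (st$pos <= length(st$toks))
    stop(sprintf("selection parse error near token '%s' (position %d) in \"%s\"",
                 st$toks[st$pos], st$pos, expression))
  which(mask)
}

sel_tokenize <- function(s) {
  s <- gsub("\\(", " ( ", s)
  s <- gsub("\\)", " ) ", s)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  if (!length(toks)) stop("empty selection expression")
  toks
}

sel_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

sel_take <- function(st) { t <- sel_peek(st); st$pos <- st$pos + 1L; t }

sel_parse_or <- function(st, top) {
  m <- sel_parse_and(st, top)
  while (!is.na(sel_peek(st)) && sel_peek(st) == "or") {
    sel_take(st)
    m <- m | sel_parse_and(st, top)
  }
  m
}

sel_parse_and <- function(st, top) {
  m <- sel_parse_unary(st, top)
  while (!is.na(sel_peek(st)) && sel_peek(st) == "and") {
    sel_take(st)
    m <- m & sel_parse_unary(st, top)
  }
  m
}

sel_parse_unary <- function(st, top) {
  t <- sel_peek(st)
  if (is.na(t))
    stop(sprintf("selection parse error: unexpected end of \"%s\"", st$src))
  if (t == "not") { sel_take(st); return(!sel_parse_unary(st, top)) }
  if (t == "(") {
    sel_take(st)
    m <- sel_parse_or(st, top)
    if (is.na(sel_peek(st)) || sel_take(st) != ")")
      stop(sprintf("selection parse error: unbalanced parenthesis (position %d)", st$pos - 1L))
    return(m)
  }
  sel_parse_term(st, top)
}

sel_parse_term <- function(st, top) {
  a <- top$atoms
  kw <- sel_take(st)
  if (kw == "water") {
    m <- logical(nrow(a)); m[as.vector(top$waters)] <- TRUE
    return(m)
  }
  val <- sel_take(st)
  if (is.na(val))
    stop(sprintf("selection parse error: '%s' needs an argument (position %d)", kw, st$pos - 1L))
  switch(kw,
    resname = a$resname == val,
    name    = a$name == val,
    element = a$element == val,
    resid   = {
      if (grepl("^[0-9]+:[0-9]+$", val)) {
        rng <- as.integer(strsplit(val, ":")[[1]])
        a$resid >= rng[1] & a$resid <= rng[2]
      } else if (grepl("^[0-9]+$", val)) {
        a$resid == as.integer(val)
      } else stop(sprintf("selection parse error: bad resid '%s' (position %d)", val, st$pos - 1L))
    },
    stop(sprintf("selection parse error: unknown keyword '%s' (position %d)", kw, st$pos - 2L))
  )
}

#' Net charge of an atom selection
#'
#' @param top A `cw_topology` with charges assigned.
#' @param idx Atom indices (default all).
#' @return Net charge in elementary charges.
#' @export
net_charge <- function(top, idx = seq_len(nrow(top$atoms))) {
  sum(top$atoms$charge[idx])
}
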