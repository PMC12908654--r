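#' Load per-atom parameters from a structured-text (YAML) file
#'
#' The parameter file carries, per (residue name, atom name) rule, the
#' mass (amu), partial charge (e), Lennard-Jones epsilon (kJ/mol) and
#' sigma (nm) plus donor/acceptor flags — everything the pairwise analysis
#' equations need; no force-field file parsing is attempted. Atom names in
#' rules may use glob wildcards (`HW*`). Every atom must be matched by
#' exactly one applicable rule set; unmatched atoms are an error listing
#' them, as are duplicate rules for the same key. Donor atoms get the
#' hydrogens of their own residue attached; water triplets are
#' (re-)detected from residue/atom names after assignment.
#'
#' @param path YAML file with a top-level `atoms:` list of rules.
#' @param top A `cw_topology` (skeleton ok).
#' @return The topology with parameters filled in.
#' @export
load_parameters <- function(path, top) {
  stopifnot(inherits(top, "cw_topology"))
  doc <- yaml::read_yaml(path)
  if (is.null(doc$atoms)) stop("parameter file has no 'atoms' section: ", path)
  rules <- doc$atoms
  keys <- vapply(rules, function(r) paste0(r$resname, "/", r$name), character(1))
  if (anyDuplicated(keys))
    stop("duplicate parameter rule(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  a <- top$atoms
  n <- nrow(a)
  matched <- logical(n)
  for (r in rules) {
    hit <- grepl(utils::glob2rx(r$resname), a$resname) &
           grepl(utils::glob2rx(r$name), a$name) & !matched
    if (!any(hit)) next
    if (!is.null(r$mass))    a$mass[hit]   <- r$mass
    if (!is.null(r$charge))  a$charge[hit] <- r$charge
    if (!is.null(r$epsilon)) a$eps[hit]    <- r$epsilon
    if (!is.null(r$sigma))   a$sigma[hit]  <- r$sigma
    if (!is.null(r$donor))    a$is_donor[hit]    <- isTRUE(r$donor)
    if (!is.null(r$acceptor)) a$is_acceptor[hit] <- isTRUE(r$acceptor)
    matched <- matched | hit
  }
  if (any(!matched))
    stop("no parameter rule matches atom(s): ",
         paste(utils::head(sprintf("%s %s%d/%s", a$name[!matched],
                                   a$resname[!matched], a$resid[!matched],
                                   which(!matched)), 10), collapse = ", "))
  bad <- which(!is.na(a$mass) & a$mass <= 0)
  if (length(bad)) stop("non-positive mass for atom(s) ", paste(bad, collapse = ", "))
  if (any(a$eps < 0, na.rm = TRUE) || any(a$sigma < 0, na.rm = TRUE))
    stop("negative Lennard-Jones parameter in ", path)
  rules_w <- if (!is.null(doc$water_rules)) {
    utils::modifyList(water_name_rules(), doc$water_rules)
  } else water_name_rules()
  dh <- attach_donor_hydrogens(a)
  top2 <- topology(a[, setdiff(names(a), "index")],
                   waters = find_waters(a, rules_w),
                   groups = top$groups, donor_hydrogens = dh)
  top2
}

# Attach, to each donor heavy atom, the hydrogen atoms of its own residue.
# Adequate for waters and simple pseudo-residue sites; a donor with no
# hydrogen in its residue is an error (the H-D-A angle is undefined).
attach_donor_hydrogens <- function(atoms) {
  dh <- list()
  donors <- which(atoms$is_donor)
  for (d in donors) {
    same <- which(atoms$resid == atoms$resid[d] &
                  atoms$resname == atoms$resname[d] &
                  atoms$element == "H")
    if (!length(same))
      stop("donor atom ", atoms$name[d], " ", atoms$resname[d], atoms$resid[d],
           " has no hydrogen in its residue")
    dh[[as.character(d)]] <- same
  }
  dh
}

#' Write a parameter file for a topology
#'
#' Emits one YAML rule per distinct (resname, atom name) with the
#' topology's current values, so a generated system can be re-analysed
#' from files alone.
#'
#' @param top A `cw_topology` with parameters assigned.
#' @param path Output path.
#' @export
write_parameters <- function(top, path) {
  a <- top$atoms
  key <- paste(a$resname, a$name)
  first <- !duplicated(key)
  rules <- lapply(which(first), function(i) {
    list(resname = a$resname[i], name = a$name[i], mass = a$mass[i],
         charge = a$charge[i], epsilon = a$eps[i], sigma = a$sigma[i],
         donor = a$is_donor[i], acceptor = a$is_acceptor[i])
  })
  yaml::write_yaml(list(atoms = rules), path, precision = 12)
  invisible(path)
}

#' Standard rigid three-site water parameter rules (TIP3P)
#'
#' Returns the YAML rule list for SOL waters named OW/HW1/HW2 with TIP3P
#' masses, charges and oxygen LJ parameters; the oxygen is both donor and
#' acceptor.
#'
#' @return A list suitable for `yaml::write_yaml(list(atoms = ...))`.
#' @export
tip3p_parameter_rules <- function() {
  list(
    list(resname = "SOL", name = "OW", mass = tip3p$mass_o, charge = tip3p$q_o,
         epsilon = tip3p$eps_o, sigma = tip3p$sigma_o,
         donor = TRUE, acceptor = TRUE),
    list(resname = "SOL", name = "HW*", mass = tip3p$mass_h, charge = tip3p$q_h,
         epsilon = 0, sigma = 0, donor = FALSE, acceptor = FALSE)
  )
}
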