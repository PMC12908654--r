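#' Read a structure file (first frame + topology skeleton)
#'
#' Supports multi-MODEL PDB, (multi-frame) GRO and extended XYZ. All
#' coordinates are converted to nm on ingest (PDB and XYZ are
#' Angstrom-based, GRO is nm-based). The returned topology is a skeleton:
#' names, elements and residues only; masses, charges, LJ parameters and
#' donor/acceptor flags are filled later by [load_parameters()].
#'
#' @param path File path.
#' @param format One of `"pdb"`, `"gro"`, `"xyz"`; default inferred from
#'   the file extension.
#' @return A list with elements `topology` (class `cw_topology`),
#'   `coords` (n x 3 matrix, nm), `box` (length-3, nm) and `time` (ps,
#'   possibly `NA`).
#' @export
read_structure <- function(path, format = guess_format(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- match.arg(format, c("pdb", "gro", "xyz"))
  fr <- switch(format,
               gro = gro_read_frames(path, first_only = TRUE),
               xyz = xyz_read_frames(path, first_only = TRUE),
               pdb = pdb_read_frames(path))
  top <- topology(fr$atoms)
  list(topology = top, coords = fr$coords[, , 1], box = fr$box[1, ],
       time = fr$times[1])
}

#' Read a trajectory file
#'
#' Reads every frame of a multi-MODEL PDB, concatenated multi-frame GRO or
#' extended XYZ trajectory. Frames must all have the same atom count; a
#' change mid-file is an error. When the format carries no time stamps
#' (PDB, or XYZ/GRO without `Time=`/`t=` annotations) frames are stamped
#' `(0, dt, 2*dt, ...)`.
#'
#' @param path File path.
#' @param topology Optional `cw_topology` to bind; defaults to the skeleton
#'   parsed from the file itself.
#' @param format `"pdb"`, `"gro"` or `"xyz"`; inferred from extension.
#' @param dt Frame interval in ps used when the file has no time stamps
#'   (default 0.1 ps, the conventional analysis output interval).
#' @return A `cw_trajectory`.
#' @export
read_trajectory <- function(path, topology = NULL, format = guess_format(path),
                            dt = 0.1) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- match.arg(format, c("pdb", "gro", "xyz"))
  fr <- switch(format,
               gro = gro_read_frames(path),
               xyz = xyz_read_frames(path),
               pdb = pdb_read_frames(path))
  if (is.null(topology)) topology <- topology(fr$atoms)
  n_fr <- dim(fr$coords)[3]
  times <- fr$times
  if (anyNA(times)) times <- (seq_len(n_fr) - 1) * dt
  trajectory(topology, fr$coords, fr$box, times)
}

#' Write a trajectory (or single frame) to file
#'
#' @param traj A `cw_trajectory`.
#' @param path Output path.
#' @param format `"pdb"`, `"gro"` or `"xyz"`; inferred from extension.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = guess_format(path)) {
  stopifnot(inherits(traj, "cw_trajectory"))
  format <- match.arg(format, c("pdb", "gro", "xyz"))
  switch(format,
         gro = gro_write(traj, path),
         xyz = xyz_write(traj, path),
         pdb = pdb_write(traj, path))
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("pdb", "gro", "xyz"))
    stop("cannot infer format from extension '", ext,
         "'; pass format = \"pdb\"|\"gro\"|\"xyz\"")
  ext
}

# ---- GRO ------------------------------------------------------------------
# Fixed columns: resid(1-5) resname(6-10) name(11-15) atomnr(16-20)
# x,y,z in nm at 21-28, 29-36, 37-44 (%8.3f).

gro_read_frames <- function(path, first_only = FALSE) {
  lines <- readLines(path)
  pos <- 1L; frames <- list(); times <- numeric(0); boxes <- list()
  atoms <- NULL
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    title <- lines[pos]
    nat <- suppressWarnings(as.integer(trimws(lines[pos + 1L])))
    if (is.na(nat))
      stop("GRO parse error at line ", pos + 1L, ": bad atom count")
    if (pos + 2L + nat > length(lines))
      stop("GRO parse error: truncated frame starting at line ", pos)
    al <- lines[(pos + 2L):(pos + 1L + nat)]
    co <- matrix(NA_real_, nat, 3)
    for (k in 1:3) {
      fld <- substr(al, 21 + (k - 1) * 8, 28 + (k - 1) * 8)
      co[, k] <- suppressWarnings(as.numeric(fld))
      if (anyNA(co[, k]))
        stop("GRO parse error at line ",
             pos + 1L + which(is.na(co[, k]))[1],
             ": malformed coordinate field")
    }
    if (is.null(atoms)) {
      atoms <- data.frame(
        name = trimws(substr(al, 11, 15)),
        resid = as.integer(trimws(substr(al, 1, 5))),
        resname = trimws(substr(al, 6, 10)),
        stringsAsFactors = FALSE)
      atoms$element <- element_from_name(atoms$name)
    } else if (length(al) != nrow(frames[[1]])) {
      stop("GRO parse error: atom count changed at line ", pos + 1L)
    }
    bx <- suppressWarnings(as.numeric(strsplit(trimws(lines[pos + 2L + nat]),
                                               "\\s+")[[1]]))
    if (length(bx) < 3 || anyNA(bx[1:3]))
      stop("GRO parse error at line ", pos + 2L + nat, ": bad box line")
    tm <- NA_real_
    m <- regmatches(title, regexec("t=\\s*([-0-9.eE+]+)", title))[[1]]
    if (length(m) == 2) tm <- as.numeric(m[2])
    frames[[length(frames) + 1L]] <- co
    boxes[[length(boxes) + 1L]] <- bx[1:3]
    times <- c(times, tm)
    pos <- pos + 3L + nat
    if (first_only) break
    while (pos <= length(lines) && !nzchar(trimws(lines[pos]))) pos <- pos + 1L
  }
  if (!length(frames)) stop("GRO parse error: no frames in ", path)
  list(atoms = atoms,
       coords = array(unlist(frames), c(nrow(frames[[1]]), 3, length(frames))),
       box = do.call(rbind, boxes),
       times = if (anyNA(times)) rep(NA_real_, length(frames)) else times)
}

gro_write <- function(traj, path) {
  a <- traj$topology$atoms
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(n_frames(traj))) {
    co <- frame_coords(traj, i)
    writeLines(sprintf("Generated by confinedwater, t= %.5f", traj$times[i]), con)
    writeLines(sprintf("%5d", nrow(a)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       a$resid %% 100000L, a$resname, a$name,
                       a$index %% 100000L, co[, 1], co[, 2], co[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", traj$box[i, 1], traj$box[i, 2],
                       traj$box[i, 3]), con)
  }
  invisible(path)
}

# ---- extended XYZ ---------------------------------------------------------
# natoms / comment with Lattice="ax 0 0 0 by 0 0 0 cz" and Time=<ps> /
# element x y z in Angstrom.

xyz_read_frames <- function(path, first_only = FALSE) {
  A <- cw_constants$A_per_nm
  lines <- readLines(path)
  pos <- 1L; frames <- list(); boxes <- list(); times <- numeric(0)
  atoms <- NULL
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat)) stop("XYZ parse error at line ", pos, ": bad atom count")
    if (pos + 1L + nat > length(lines))
      stop("XYZ parse error: truncated frame at line ", pos)
    comment <- lines[pos + 1L]
    lat <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1]]
    if (length(lat) != 2)
      stop("XYZ parse error at line ", pos + 1L, ": missing Lattice=")
    lv <- as.numeric(strsplit(trimws(lat[2]), "\\s+")[[1]])
    if (length(lv) != 9 || anyNA(lv))
      stop("XYZ parse error at line ", pos + 1L, ": bad Lattice")
    bx <- c(lv[1], lv[5], lv[9]) / A
    tm <- NA_real_
    m <- regmatches(comment, regexec("Time=([-0-9.eE+]+)", comment))[[1]]
    if (length(m) == 2) tm <- as.numeric(m[2])
    al <- strsplit(trimws(lines[(pos + 2L):(pos + 1L + nat)]), "\\s+")
    bad <- which(lengths(al) < 4L)
    if (length(bad))
      stop("XYZ parse error at line ", pos + 1L + bad[1], ": short atom line")
    sp <- vapply(al, `[`, character(1), 1L)
    co <- t(vapply(al, function(f) as.numeric(f[2:4]), numeric(3))) / A
    if (anyNA(co)) stop("XYZ parse error: malformed coordinate in frame at line ", pos)
    if (is.null(atoms)) {
      atoms <- data.frame(name = sp, element = sp,
                          resid = seq_along(sp), resname = "XYZ",
                          stringsAsFactors = FALSE)
    } else if (nat != nrow(atoms)) {
      stop("XYZ parse error: atom count changed at line ", pos)
    }
    frames[[length(frames) + 1L]] <- co
    boxes[[length(boxes) + 1L]] <- bx
    times <- c(times, tm)
    pos <- pos + 2L + nat
    if (first_only) break
  }
  if (!length(frames)) stop("XYZ parse error: no frames in ", path)
  list(atoms = atoms,
       coords = array(unlist(frames), c(nrow(atoms), 3, length(frames))),
       box = do.call(rbind, boxes),
       times = if (anyNA(times)) rep(NA_real_, length(frames)) else times)
}

xyz_write <- function(traj, path) {
  A <- cw_constants$A_per_nm
  a <- traj$topology$atoms
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(n_frames(traj))) {
    co <- frame_coords(traj, i) * A
    b <- traj$box[i, ] * A
    writeLines(sprintf("%d", nrow(a)), con)
    writeLines(sprintf(
      'Lattice="%.6f 0 0 0 %.6f 0 0 0 %.6f" Properties=species:S:1:pos:R:3 Time=%.6f',
      b[1], b[2], b[3], traj$times[i]), con)
    writeLines(sprintf("%-3s %12.6f %12.6f %12.6f", a$element, co[, 1],
                       co[, 2], co[, 3]), con)
  }
  invisible(path)
}

# ---- PDB ------------------------------------------------------------------
# Read with bio3d (multi-MODEL); CRYST1 parsed separately since bio3d does
# not carry the box through. Written by hand (MODEL/ENDMDL blocks).

pdb_read_frames <- function(path) {
  A <- cw_constants$A_per_nm
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_fr <- nrow(xyz); nat <- ncol(xyz) / 3
  co <- array(NA_real_, c(nat, 3, n_fr))
  for (i in seq_len(n_fr))
    co[, , i] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE) / A
  cl <- grep("^CRYST1", readLines(path), value = TRUE)
  box <- if (length(cl)) {
    as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                 substr(cl[1], 25, 33))) / A
  } else {
    # no CRYST1: bounding extent + 1 nm margin, a conventional fallback
    apply(co, 2, function(v) diff(range(v))) + 1
  }
  el <- trimws(pdb$atom$elesy)
  el[is.na(el) | el == ""] <- element_from_name(trimws(pdb$atom$elety[is.na(el) | el == ""]))
  atoms <- data.frame(name = trimws(pdb$atom$elety),
                      element = el,
                      resid = pdb$atom$resno,
                      resname = trimws(pdb$atom$resid),
                      stringsAsFactors = FALSE)
  list(atoms = atoms, coords = co,
       box = matrix(box, n_fr, 3, byrow = TRUE),
       times = rep(NA_real_, n_fr))
}

pdb_write <- function(traj, path) {
  A <- cw_constants$A_per_nm
  a <- traj$topology$atoms
  con <- file(path, "w"); on.exit(close(con))
  b <- traj$box[1, ] * A
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     b[1], b[2], b[3], 90, 90, 90), con)
  multi <- n_frames(traj) > 1L
  for (i in seq_len(n_frames(traj))) {
    if (multi) writeLines(sprintf("MODEL %8d", i), con)
    co <- frame_coords(traj, i) * A
    nm <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
    writeLines(sprintf("ATOM  %5d %-4s %-4s %4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       a$index %% 100000L, substr(nm, 1, 4), a$resname,
                       a$resid %% 10000L, co[, 1], co[, 2], co[, 3],
                       1, 0, a$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

element_from_name <- function(name) {
  e <- sub("^[0-9]*", "", name)
  e <- substr(e, 1, 1)
  toupper(e)
}
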