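# Residual hydrophobic mismatch (RHM) energetics.
#
# The bilayer's acyl-chain zone is idealized as a planar slab normal to z.
# A residue pays an energy penalty proportional to its mismatched solvent-
# accessible area: for hydrophobic residues the accessible area exposed
# outside the slab, for polar residues the accessible area buried inside
# it. Ser/Thr are never penalized (side-chain polar groups H-bond to the
# helix backbone); Trp and Arg/Lys near a slab boundary are exempt
# (interfacial accommodation and snorkeling, respectively).

# element -> van der Waals radius (Angstrom), NACCESS-compatible values
.element_radii <- c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, P = 1.80,
                    H = 1.00)
.default_element_radius <- 1.80

# residues penalized as hydrophobic; everything else is polar unless exempt
.hydrophobic_set <- c("ALA", "VAL", "LEU", "ILE", "PHE", "MET", "PRO",
                      "GLY", "CYS")

#' Ideal membrane hydrophobic-core slab
#'
#' @param z_lower,z_upper Bounds of the hydrophobic core along the membrane
#'   normal (z), in Angstrom. Default is a 30 Angstrom slab centred at 0.
#' @param headgroup_margin Width of the interfacial region adjacent to each
#'   bound within which Trp and Arg/Lys are exempted (default 3 Angstrom).
#' @return Object of class `membrane_slab`.
#' @export
membrane_slab <- function(z_lower = -15, z_upper = 15,
                          headgroup_margin = 3) {
  stop_if_not_scalar(z_lower, "z_lower")
  stop_if_not_scalar(z_upper, "z_upper")
  stop_if_not_scalar(headgroup_margin, "headgroup_margin")
  if (z_lower >= z_upper) stop("z_lower must be < z_upper", call. = FALSE)
  if (headgroup_margin < 0) stop("headgroup_margin must be >= 0",
                                 call. = FALSE)
  structure(list(z_lower = z_lower, z_upper = z_upper,
                 headgroup_margin = headgroup_margin),
            class = "membrane_slab")
}

#' Build a structure model from atom records
#'
#' A light container for the coordinates the RHM calculation needs. Atoms
#' are supplied as a data frame with columns `element`, `resname` (3-letter
#' code), `resno`, `chain`, `x`, `y`, `z` and optionally `radius` and
#' `name` (atom name; used to locate side-chain positions). Radii default
#' to an element-based NACCESS-compatible table. The structure is assumed
#' oriented with the membrane normal along z.
#'
#' @param atoms Atom data frame (see Description).
#' @param helices Named list of `c(first_resno, last_resno)` ranges
#'   defining the transmembrane helices.
#' @return Object of class `structure_model`.
#' @seealso [read_structure_pdb()], [toy_helix_structure()]
#' @export
structure_model <- function(atoms, helices = list()) {
  need <- c("element", "resname", "resno", "x", "y", "z")
  if (!is.data.frame(atoms) || !all(need %in% names(atoms)))
    stop("`atoms` must contain columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (nrow(atoms) < 1L) stop("need >= 1 atom", call. = FALSE)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("coordinates must be finite", call. = FALSE)
  if (is.null(atoms$chain)) atoms$chain <- "A"
  if (is.null(atoms$name)) atoms$name <- atoms$element
  if (is.null(atoms$radius)) {
    r <- .element_radii[toupper(atoms$element)]
    r[is.na(r)] <- .default_element_radius
    atoms$radius <- unname(r)
  }
  for (h in helices) {
    if (length(h) != 2L || h[1L] > h[2L])
      stop("helix ranges must be c(first_resno, last_resno)", call. = FALSE)
  }
  structure(list(atoms = atoms, helices = helices),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("Structure model: %d atoms, %d residues, %d helix range(s)\n",
              nrow(x$atoms), length(unique(x$atoms$resno)),
              length(x$helices)))
  invisible(x)
}

#' Read a PDB file into a structure model
#'
#' Thin wrapper over [bio3d::read.pdb()] keeping protein ATOM records
#' (hydrogens excluded by default, matching common SASA practice).
#'
#' @param path PDB file path.
#' @param helices Named list of residue-number ranges (see
#'   [structure_model()]).
#' @param keep_hydrogens Keep hydrogen atoms (default FALSE).
#' @return A `structure_model`.
#' @export
read_structure_pdb <- function(path, helices = list(),
                               keep_hydrogens = FALSE) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(trimws(a$elety), 1L, 1L)
  keep <- if (keep_hydrogens) rep(TRUE, nrow(a)) else toupper(elem) != "H"
  a <- a[keep, , drop = FALSE]; elem <- elem[keep]
  structure_model(
    data.frame(element = toupper(trimws(elem)), resname = a$resid,
               resno = a$resno, chain = a$chain, name = trimws(a$elety),
               x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE),
    helices = helices)
}

# deterministic, nearly uniform points on the unit sphere (Fibonacci spiral)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area by sphere sampling
#'
#' Shrake-Rupley style SASA: each atom's expanded sphere (van der Waals
#' radius + probe) is sampled with a deterministic Fibonacci point set; a
#' point is accessible when it lies outside every neighbouring expanded
#' sphere. Each accessible point carries an equal share of the expanded
#' sphere's area; the z-coordinates of accessible points are retained so
#' the surface can later be partitioned by a membrane slab.
#'
#' @param structure A `structure_model`.
#' @param probe_radius Probe radius in Angstrom (default 1.4, water).
#' @param n_points Sample points per atom (default 960).
#' @return Object of class `sasa_result`: per-atom `area` (Angstrom^2),
#'   `point_area` (area per accessible point), `point_z` (list of
#'   accessible-point z coordinates per atom), and a per-residue summary
#'   data frame `residues` (`resno`, `resname`, `area`).
#' @examples
#' a <- data.frame(element = "C", resname = "ALA", resno = 1,
#'                 x = 0, y = 0, z = 0, radius = 1.9)
#' compute_sasa(structure_model(a))$area  # 4*pi*(1.9+1.4)^2
#' @export
compute_sasa <- function(structure, probe_radius = 1.4, n_points = 960L) {
  stopifnot(inherits(structure, "structure_model"))
  stop_if_not_scalar(probe_radius, "probe_radius", positive = TRUE)
  at <- structure$atoms
  n <- nrow(at)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rexp_ <- at$radius + probe_radius
  # identical coincident atoms confuse the occlusion rule
  if (n > 1L) {
    d0 <- as.matrix(stats::dist(xyz))
    diag(d0) <- Inf
    if (any(d0 < 1e-9))
      warning("overlapping identical atom positions detected")
  }
  pts <- fibonacci_sphere(as.integer(n_points))
  area <- numeric(n)
  point_z <- vector("list", n)
  point_area <- 4 * pi * rexp_^2 / n_points
  for (i in seq_len(n)) {
    p <- sweep(pts * rexp_[i], 2L, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    if (n > 1L) {
      nb <- which(d0[i, ] < rexp_[i] + rexp_)
      for (j in nb) {
        if (!any(acc)) break
        dz <- p[acc, 1L] - xyz[j, 1L]
        dy <- p[acc, 2L] - xyz[j, 2L]
        dzz <- p[acc, 3L] - xyz[j, 3L]
        acc[acc] <- dz^2 + dy^2 + dzz^2 >= rexp_[j]^2
      }
    }
    area[i] <- sum(acc) * point_area[i]
    point_z[[i]] <- p[acc, 3L]
  }
  key <- paste(at$chain, at$resno)
  first <- !duplicated(key)          # keep sequence order
  area_by_res <- tapply(area, key, sum)
  residues <- data.frame(resno = at$resno[first], chain = at$chain[first],
                         resname = at$resname[first],
                         area = as.numeric(area_by_res[key[first]]))
  structure(
    list(area = area, point_area = point_area, point_z = point_z,
         residues = residues,
         probe_radius = probe_radius, n_points = as.integer(n_points)),
    class = "sasa_result")
}

side_chain_z <- function(atoms) {
  # representative side-chain z per residue: CB, falling back to CA,
  # falling back to the residue centroid; names are "chain resno" keys
  split_idx <- split(seq_len(nrow(atoms)),
                     paste(atoms$chain, atoms$resno))
  vapply(split_idx, function(ix) {
    nm <- atoms$name[ix]
    cb <- ix[nm == "CB"]
    if (length(cb)) return(atoms$z[cb[1L]])
    ca <- ix[nm == "CA"]
    if (length(ca)) return(atoms$z[ca[1L]])
    mean(atoms$z[ix])
  }, numeric(1))
}

#' Classify a residue for the mismatch penalty
#'
#' Ser and Thr are always exempt. Trp, Arg and Lys are exempt when the
#' side-chain reference position lies within `headgroup_margin` of either
#' slab boundary (interfacial Trp accommodates at the interface; Arg/Lys
#' snorkel towards the headgroups). Remaining residues are `"hydrophobic"`
#' when in the hydrophobic set (default Ala, Val, Leu, Ile, Phe, Met, Pro,
#' Gly, Cys) and `"polar"` otherwise; unknown residue names are treated as
#' polar with a warning.
#'
#' @param resname 3-letter residue code(s).
#' @param z_side Side-chain reference z (Cb, falling back to Ca), Angstrom.
#' @param slab A [membrane_slab()].
#' @param hydrophobic_set Character vector of residues penalized as
#'   hydrophobic (overridable).
#' @return Character vector: `"hydrophobic"`, `"polar"` or `"exempt"`.
#' @export
classify_residue <- function(resname, z_side, slab = membrane_slab(),
                             hydrophobic_set = .hydrophobic_set) {
  resname <- toupper(resname)
  known <- c(hydrophobic_set, "SER", "THR", "TRP", "ARG", "LYS",
             "ASN", "ASP", "GLN", "GLU", "HIS", "TYR")
  if (any(!resname %in% known))
    warning("unknown residue name(s) treated as polar: ",
            paste(unique(resname[!resname %in% known]), collapse = ", "))
  near_boundary <- pmin(abs(z_side - slab$z_lower),
                        abs(z_side - slab$z_upper)) <= slab$headgroup_margin
  out <- ifelse(resname %in% hydrophobic_set, "hydrophobic", "polar")
  out[resname %in% c("SER", "THR")] <- "exempt"
  out[resname %in% c("TRP", "ARG", "LYS") & near_boundary] <- "exempt"
  out
}

#' Per-residue mismatch areas against a membrane slab
#'
#' Partitions each residue's accessible surface points by z against the
#' hydrophobic-core slab and applies the penalty rule: for hydrophobic
#' residues the mismatched area `SA_res` is the accessible area outside
#' the slab (`SA_mem`); for polar residues it is the accessible area
#' inside the slab (`SA_prot - SA_mem`); exempt residues contribute 0.
#'
#' @param structure A `structure_model`.
#' @param slab A [membrane_slab()].
#' @param sasa A `sasa_result` from [compute_sasa()]; computed on demand
#'   when `NULL`.
#' @inheritParams classify_residue
#' @param ... Passed to [compute_sasa()] when `sasa` is `NULL`.
#' @return Data frame with one row per residue: `resno`, `resname`,
#'   `class`, `sa_prot`, `sa_mem`, `sa_res` (Angstrom^2).
#' @export
residue_exposure <- function(structure, slab = membrane_slab(),
                             sasa = NULL,
                             hydrophobic_set = .hydrophobic_set, ...) {
  stopifnot(inherits(structure, "structure_model"),
            inherits(slab, "membrane_slab"))
  if (is.null(sasa)) sasa <- compute_sasa(structure, ...)
  at <- structure$atoms
  resnos <- sasa$residues$resno
  res_key <- paste(sasa$residues$chain, resnos)
  atom_key <- paste(at$chain, at$resno)
  zs <- side_chain_z(at)[res_key]
  cls <- classify_residue(sasa$residues$resname, zs, slab,
                          hydrophobic_set)
  inside <- outside <- numeric(length(resnos))
  for (k in seq_along(resnos)) {
    ix <- which(atom_key == res_key[k])
    ain <- aout <- 0
    for (i in ix) {
      z <- sasa$point_z[[i]]
      if (!length(z)) next
      nin <- sum(z >= slab$z_lower & z <= slab$z_upper)
      ain <- ain + nin * sasa$point_area[i]
      aout <- aout + (length(z) - nin) * sasa$point_area[i]
    }
    inside[k] <- ain; outside[k] <- aout
  }
  sa_prot <- inside + outside
  sa_mem <- outside   # area not covered when the slab joins the solute
  sa_res <- ifelse(cls == "hydrophobic", sa_mem,
                   ifelse(cls == "polar", sa_prot - sa_mem, 0))
  data.frame(resno = resnos, resname = sasa$residues$resname,
             class = cls, sa_prot = sa_prot, sa_mem = sa_mem,
             sa_res = sa_res)
}

#' RHM energy of a transmembrane helix
#'
#' Sums the per-residue mismatch areas of the helix and scales by the
#' proportionality coefficient: `E = sigma_res * sum(SA_res)`, with
#' `sigma_res = 0.0028` kcal/(mol Angstrom^2) by default.
#'
#' @param exposure Per-residue exposure table from [residue_exposure()].
#' @param range `c(first_resno, last_resno)` of the helix; `NULL` uses all
#'   residues.
#' @param name Helix name for the report.
#' @param sigma_res Energy per mismatched area, kcal/(mol Angstrom^2).
#' @return Object of class `helix_rhm`: `helix`, `energy` (kcal/mol),
#'   `n_res`, `residues` (per-residue contributions).
#' @export
helix_rhm_energy <- function(exposure, range = NULL, name = "helix",
                             sigma_res = 0.0028) {
  rows <- if (is.null(range)) exposure
          else exposure[exposure$resno >= range[1L] &
                        exposure$resno <= range[2L], , drop = FALSE]
  if (!nrow(rows)) {
    warning("empty helix `", name, "`: zero-energy result")
    return(structure(list(helix = name, energy = 0, n_res = 0L,
                          residues = rows), class = "helix_rhm"))
  }
  rows$energy <- sigma_res * rows$sa_res
  structure(
    list(helix = name, energy = sum(rows$energy), n_res = nrow(rows),
         residues = rows),
    class = "helix_rhm")
}

#' @export
print.helix_rhm <- function(x, ...) {
  cat(sprintf("%s: RHM = %.3f kcal/mol over %d residues\n",
              x$helix, x$energy, x$n_res))
  invisible(x)
}

#' Full RHM profile of a structure
#'
#' Convenience wrapper running [compute_sasa()], [residue_exposure()] and
#' [helix_rhm_energy()] for every helix range of the structure (the whole
#' chain is treated as one helix, with a warning, when no ranges are
#' defined).
#'
#' @inheritParams residue_exposure
#' @inheritParams helix_rhm_energy
#' @inheritParams compute_sasa
#' @return List with `helices` (data frame: helix, energy_kcal_mol,
#'   n_res), `exposure` (per-residue table) and `per_helix` (list of
#'   `helix_rhm` objects).
#' @export
rhm_profile <- function(structure, slab = membrane_slab(),
                        probe_radius = 1.4, n_points = 960L,
                        sigma_res = 0.0028,
                        hydrophobic_set = .hydrophobic_set) {
  sasa <- compute_sasa(structure, probe_radius, n_points)
  expo <- residue_exposure(structure, slab, sasa, hydrophobic_set)
  helices <- structure$helices
  if (!length(helices)) {
    warning("no helix ranges defined; treating the whole chain as one helix")
    helices <- list(all = range(expo$resno))
  }
  per <- lapply(names(helices), function(nm)
    helix_rhm_energy(expo, helices[[nm]], nm, sigma_res))
  names(per) <- names(helices)
  list(
    helices = data.frame(
      helix = names(helices),
      energy_kcal_mol = vapply(per, function(h) h$energy, numeric(1)),
      n_res = vapply(per, function(h) h$n_res, integer(1))),
    exposure = expo, per_helix = per)
}

#' Replicate-bootstrap SD of an RHM energy
#'
#' Reproduces the replicate-level error estimate used with small numbers of
#' independent simulation replicates: draw 3 of the `>= 4` replicate
#' energies without replacement, average them, repeat 4 times, and report
#' the SD of the 4 means.
#'
#' @param replicate_values Numeric vector of >= 4 per-replicate energies.
#' @param seed RNG seed (mandatory; the caller's RNG state is untouched).
#' @param n_draws Number of resampled means (default 4).
#' @param n_pick Replicates per draw (default 3).
#' @return The bootstrap SD.
#' @export
bootstrap_sd <- function(replicate_values, seed, n_draws = 4L,
                         n_pick = 3L) {
  if (length(replicate_values) < 4L)
    stop("need >= 4 replicate values", call. = FALSE)
  with_local_seed(seed, {
    means <- vapply(seq_len(n_draws), function(i)
      mean(sample(replicate_values, n_pick, replace = FALSE)),
      numeric(1))
    sd(means)
  })
}

#' Compare per-helix RHM energies between two constructs
#'
#' For each helix, reports the mean difference in replicate RHM energies
#' between construct A and construct B and the two-sided p-value of the
#' classic (pooled-variance) unpaired t-test. Degenerate helices with zero
#' variance in both groups get p = 1 when the means agree and p = 0
#' otherwise.
#'
#' @param profile_a,profile_b Matrices or data frames of replicate energies
#'   (helices in rows, replicates in columns; row names are helix names).
#' @return Data frame: `helix`, `mean_a`, `mean_b`, `delta`
#'   (A minus B, kcal/mol), `p_value`.
#' @export
compare_constructs <- function(profile_a, profile_b) {
  a <- as.matrix(profile_a); b <- as.matrix(profile_b)
  if (nrow(a) != nrow(b))
    stop("constructs must share the same helices", call. = FALSE)
  if (ncol(a) < 2L || ncol(b) < 2L)
    stop("need >= 2 replicates per construct", call. = FALSE)
  helix <- rownames(a) %||% paste0("TM", seq_len(nrow(a)))
  out <- lapply(seq_len(nrow(a)), function(i) {
    va <- a[i, ]; vb <- b[i, ]
    p <- tryCatch(
      t.test(va, vb, var.equal = TRUE)$p.value,
      error = function(e)
        if (isTRUE(all.equal(mean(va), mean(vb)))) 1 else 0)
    data.frame(helix = helix[i], mean_a = mean(va), mean_b = mean(vb),
               delta = mean(va) - mean(vb), p_value = p)
  })
  do.call(rbind, out)
}

#' Per-residue RHM from an externally computed accessibility table
#'
#' Accepts an RSA-style table of per-residue accessible areas computed
#' elsewhere (e.g. with the bilayer included in the solute) and applies the
#' same penalty and exemption rules as [residue_exposure()], bypassing the
#' internal SASA and slab partition. The table needs columns `resno`,
#' `resname`, `sa_mem`, `sa_prot` and either `class` or `z_side` (from
#' which the class is derived against `slab`).
#'
#' @param table Data frame (see Description) or path to its CSV.
#' @param slab A [membrane_slab()]; used only when `class` is absent.
#' @inheritParams classify_residue
#' @return Per-residue exposure table in the [residue_exposure()] format.
#' @export
exposure_from_rsa <- function(table, slab = membrane_slab(),
                              hydrophobic_set = .hydrophobic_set) {
  if (is.character(table)) table <- read.csv(table)
  need <- c("resno", "resname", "sa_mem", "sa_prot")
  if (!all(need %in% names(table)))
    stop("RSA table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  cls <- if ("class" %in% names(table)) table$class
         else if ("z_side" %in% names(table))
           classify_residue(table$resname, table$z_side, slab,
                            hydrophobic_set)
         else stop("RSA table needs a `class` or `z_side` column",
                   call. = FALSE)
  sa_res <- ifelse(cls == "hydrophobic", table$sa_mem,
                   ifelse(cls == "polar", table$sa_prot - table$sa_mem, 0))
  data.frame(resno = table$resno, resname = toupper(table$resname),
             class = cls, sa_prot = table$sa_prot, sa_mem = table$sa_mem,
             sa_res = pmax(sa_res, 0))
}
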