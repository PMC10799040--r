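#' Build a topology from an atom table
#'
#' A topology is the static per-atom record accompanying a trajectory: one
#' row per atom with element, site name, partial charge (e), Lennard-Jones
#' parameters (epsilon kcal/mol, sigma A), molecule id, species label and a
#' hydrogen-bond role tag, plus named atom-index groups. Role tags drive the
#' HBA/HBD/water group decomposition used by the interaction-energy and
#' stability analyses.
#'
#' @param atoms Data frame with columns `element`, `name`, `charge`,
#'   `lj_epsilon`, `lj_sigma`, `molecule_id`, `species`, `role`. `role` must
#'   be one of `"HBA"`, `"HBD"`, `"water"`, `"other"`.
#' @param groups Named list of integer atom-index vectors (1-based). Groups
#'   for each species, role and element are added automatically.
#' @return An object of class `topology`: list with tibble `atoms` and list
#'   `groups`.
#' @export
topology <- function(atoms, groups = list()) {
  atoms <- tibble::as_tibble(atoms)
  req <- c("element", "name", "charge", "lj_epsilon", "lj_sigma",
           "molecule_id", "species", "role")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atom table missing column(s): ",
                         paste(miss, collapse = ", "))
  bad_role <- setdiff(unique(atoms$role), c("HBA", "HBD", "water", "other"))
  if (length(bad_role)) {
    stop("unknown role tag(s): ", paste(bad_role, collapse = ", "),
         " (must be HBA, HBD, water or other)")
  }
  if (any(atoms$lj_epsilon < 0)) stop("lj_epsilon must be >= 0")
  if (any(atoms$lj_sigma <= 0)) stop("lj_sigma must be positive")
  # molecule ids must group atoms contiguously
  rl <- rle(atoms$molecule_id)
  if (anyDuplicated(rl$values)) {
    stop("molecule_id must group atoms contiguously")
  }
  n <- nrow(atoms)
  if (anyDuplicated(names(groups))) {
    stop("duplicate group name in topology groups")
  }
  for (g in names(groups)) {
    gi <- groups[[g]]
    if (length(gi) && (any(gi < 1) || any(gi > n))) {
      stop("group '", g, "' contains invalid atom indices")
    }
    groups[[g]] <- as.integer(gi)
  }
  auto <- list()
  for (sp in unique(atoms$species)) auto[[sp]] <- which(atoms$species == sp)
  for (ro in unique(atoms$role)) auto[[ro]] <- which(atoms$role == ro)
  groups <- utils::modifyList(auto, groups)
  structure(list(atoms = atoms, groups = groups), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology> %d atoms, %d molecules, species: %s\n",
              nrow(x$atoms), length(unique(x$atoms$molecule_id)),
              paste(unique(x$atoms$species), collapse = ", ")))
  invisible(x)
}

n_atoms <- function(top) nrow(top$atoms)

#' Select atom indices from a topology
#'
#' @param top A [topology()].
#' @param species,role,element,name Optional filters; an atom must match all
#'   that are given.
#' @param group Optional named group; returned as-is (other filters then
#'   apply within it).
#' @return Integer vector of atom indices.
#' @export
select_atoms <- function(top, species = NULL, role = NULL, element = NULL,
                         name = NULL, group = NULL) {
  idx <- seq_len(n_atoms(top))
  if (!is.null(group)) {
    if (!group %in% names(top$groups)) stop("no such group: ", group)
    idx <- top$groups[[group]]
  }
  a <- top$atoms
  if (!is.null(species)) idx <- idx[a$species[idx] %in% species]
  if (!is.null(role)) idx <- idx[a$role[idx] %in% role]
  if (!is.null(element)) idx <- idx[a$element[idx] %in% element]
  if (!is.null(name)) idx <- idx[a$name[idx] %in% name]
  idx
}

#' Pair donor hydrogens with their parent heavy atoms
#'
#' Hydrogen-bond detection needs the covalent donor-hydrogen pairing. Each
#' hydrogen in `hydrogens` is matched to the unique atom of `donors` in the
#' same molecule; a hydrogen whose molecule contains no (or more than one)
#' candidate donor is an error.
#'
#' @param top A [topology()].
#' @param donors,hydrogens Integer atom-index vectors.
#' @return Tibble with columns `donor`, `hydrogen`.
#' @export
donor_hydrogen_map <- function(top, donors, hydrogens) {
  mol <- top$atoms$molecule_id
  dm <- split(donors, mol[donors])
  rows <- lapply(hydrogens, function(h) {
    cand <- dm[[as.character(mol[h])]]
    if (is.null(cand) || length(cand) == 0) {
      stop("hydrogen atom ", h, " has no parent donor in its molecule")
    }
    if (length(cand) > 1) {
      stop("hydrogen atom ", h, " matches multiple donors; ",
           "supply an explicit donor map")
    }
    c(donor = cand, hydrogen = h)
  })
  m <- do.call(rbind, rows)
  tibble::tibble(donor = as.integer(m[, 1]), hydrogen = as.integer(m[, 2]))
}

#' Read a topology from a YAML file
#'
#' The schema has two top-level keys. `atoms`: a list of records with fields
#' `element`, `name`, `charge`, `lj_epsilon`, `lj_sigma`, `molecule_id`,
#' `species`, `role`. `groups` (optional): a mapping from group name to a
#' list of 1-based atom indices.
#'
#' @param path Path to the YAML file.
#' @return A [topology()].
#' @export
read_topology <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$atoms)) stop("topology file has no 'atoms' key: ", path)
  atoms <- dplyr::bind_rows(lapply(doc$atoms, tibble::as_tibble))
  groups <- doc$groups %||% list()
  if (anyDuplicated(names(groups))) {
    stop("duplicate group name in topology file: ",
         names(groups)[duplicated(names(groups))][1])
  }
  topology(atoms, lapply(groups, as.integer))
}

#' Write a topology to a YAML file
#'
#' @param top A [topology()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(top, path) {
  doc <- list(
    atoms = lapply(seq_len(n_atoms(top)), function(i) {
      as.list(top$atoms[i, c("element", "name", "charge", "lj_epsilon",
                             "lj_sigma", "molecule_id", "species", "role")])
    }),
    groups = lapply(top$groups, as.integer)
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
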