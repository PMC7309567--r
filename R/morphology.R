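#' Build a soma-plus-cable morphology with named recording sites
#'
#' Constructs a reduced morphology consisting of a cylindrical soma and a
#' single unbranched dendritic cable, with recording sites placed at the
#' requested path distances from the soma and given the requested local
#' diameters.  This is the reduced stand-in used throughout the package for
#' full reconstructed morphologies: it preserves a somatic site plus four
#' increasingly distant dendritic sites (named `S`, `D1` ... `Dk`).
#'
#' The dendritic cable is divided into `n_dend` equal-length compartments;
#' the diameter of each compartment is linearly interpolated between the
#' site diameters along the path, so each requested site sits in a
#' compartment with (approximately) the requested diameter.
#'
#' @param n_sites Number of recording sites (soma included).  `n_sites = 1`
#'   gives a soma-only morphology.
#' @param site_diameters Numeric vector of length `n_sites`: diameter (um)
#'   at the soma and at each dendritic site.
#' @param site_distances Numeric vector of length `n_sites`: path distance
#'   (um) from the soma centre; the first entry must be 0 (soma) and the
#'   rest strictly increasing.
#' @param soma_length Soma cylinder length (um).
#' @param n_dend Number of dendritic compartments for the cable.
#' @param axial_resistivity Axial resistivity (ohm cm).
#' @param capacitance Specific membrane capacitance (uF/cm^2).
#' @return An object of class `ivl_morphology`: a list with a `compartments`
#'   tibble (one row per compartment: `comp`, `parent`, `region`, `length`,
#'   `diameter`, `area`, `path_distance`), a named integer vector `sites`
#'   mapping site names to compartment indices, and the passive constants.
#' @examples
#' m <- build_chain_morphology(
#'   5, c(9.84, 1.92, 0.82, 0.94, 0.75), c(0, 50, 100, 150, 200))
#' m$sites
#' @export
build_chain_morphology <- function(n_sites,
                                   site_diameters,
                                   site_distances,
                                   soma_length = 10,
                                   n_dend = 20,
                                   axial_resistivity = 150,
                                   capacitance = 1) {
  stopifnot(n_sites >= 1,
            length(site_diameters) == n_sites,
            length(site_distances) == n_sites)
  if (any(site_diameters <= 0)) {
    stop("site diameters must be positive", call. = FALSE)
  }
  if (site_distances[1] != 0) {
    stop("the first site is the soma and must be at path distance 0",
         call. = FALSE)
  }
  if (n_sites > 1 && any(diff(site_distances) <= 0)) {
    stop("site distances must be strictly increasing", call. = FALSE)
  }

  soma <- tibble::tibble(
    comp = 1L, parent = NA_integer_, region = "soma",
    length = soma_length, diameter = site_diameters[1],
    path_distance = 0
  )

  if (n_sites == 1) {
    comps <- soma
    sites <- c(S = 1L)
  } else {
    total_len <- site_distances[n_sites]
    edges <- seq(0, total_len, length.out = n_dend + 1)
    mid <- (edges[-1] + edges[-(n_dend + 1)]) / 2
    diam <- stats::approx(site_distances, site_diameters, xout = mid,
                          rule = 2)$y
    dend <- tibble::tibble(
      comp = seq_len(n_dend) + 1L,
      parent = c(1L, seq_len(n_dend - 1) + 1L),
      region = "dend",
      length = diff(edges),
      diameter = diam,
      path_distance = mid
    )
    comps <- dplyr::bind_rows(soma, dend)
    site_comp <- vapply(site_distances[-1], function(d) {
      which.min(abs(mid - d)) + 1L
    }, integer(1))
    sites <- c(1L, site_comp)
    names(sites) <- c("S", paste0("D", seq_len(n_sites - 1)))
  }

  comps$area <- pi * comps$diameter * comps$length

  structure(
    list(
      compartments = comps,
      sites = sites,
      axial_resistivity = axial_resistivity,
      capacitance = capacitance
    ),
    class = "ivl_morphology"
  )
}

#' Read an SWC morphology file
#'
#' Parses the standard 7-column SWC format (`id type x y z radius parent`,
#' `#` comments) into the package's morphology representation.  Each SWC
#' point (except the root) becomes one compartment spanning the segment from
#' its parent point to itself; region labels are mapped from SWC type codes
#' (1 = soma, 2 = axon, 3/4 = dend, others rejected).  Path distances are
#' accumulated along the 3D point chain.
#'
#' @param source Path to an SWC file, or a character vector of SWC lines.
#' @inheritParams build_chain_morphology
#' @return An `ivl_morphology` object.  The soma point becomes the root
#'   compartment; its length is taken as twice its radius.
#' @export
load_swc <- function(source, axial_resistivity = 150, capacitance = 1) {
  lines <- if (length(source) == 1 && !grepl("\n", source) &&
                 file.exists(source)) {
    readLines(source)
  } else {
    unlist(strsplit(source, "\n"))
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("no SWC records found", call. = FALSE)

  fields <- do.call(rbind, lapply(strsplit(lines, "[[:space:]]+"), function(x) {
    if (length(x) != 7) stop("malformed SWC record: ", paste(x, collapse = " "),
                             call. = FALSE)
    as.numeric(x)
  }))
  id <- as.integer(fields[, 1]); type <- as.integer(fields[, 2])
  xyz <- fields[, 3:5, drop = FALSE]; radius <- fields[, 6]
  parent <- as.integer(fields[, 7])

  if (anyDuplicated(id)) stop("duplicate SWC node ids", call. = FALSE)
  known <- c(1L, 2L, 3L, 4L)
  if (any(!type %in% known)) {
    bad <- id[!type %in% known]
    stop("unknown SWC type codes at node ids: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(parent, id)
  orphan <- parent != -1 & is.na(idx)
  if (any(orphan)) {
    stop("orphan SWC nodes (missing parent): ",
         paste(id[orphan], collapse = ", "), call. = FALSE)
  }
  if (sum(parent == -1) != 1) {
    stop("SWC tree must have exactly one root", call. = FALSE)
  }
  if (any(radius <= 0)) stop("non-positive radius in SWC", call. = FALSE)

  # topological order (parents before children); also detects cycles
  n <- length(id)
  order <- integer(0)
  placed <- rep(FALSE, n)
  remaining <- seq_len(n)
  repeat {
    ready <- remaining[vapply(remaining, function(i) {
      parent[i] == -1 || placed[idx[i]]
    }, logical(1))]
    if (length(ready) == 0) {
      if (length(remaining) > 0)
        stop("cyclic parent references in SWC at node ids: ",
             paste(id[remaining], collapse = ", "), call. = FALSE)
      break
    }
    placed[ready] <- TRUE
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
    if (length(remaining) == 0) break
  }

  rank <- match(seq_len(n), order)
  region_of <- c("soma", "axon", "dend", "dend")

  comps <- tibble::tibble(
    comp = rank,
    parent = ifelse(parent == -1, NA_integer_, rank[idx]),
    region = region_of[type],
    length = NA_real_, diameter = 2 * radius,
    path_distance = NA_real_
  )[order(rank), ]

  xyz <- xyz[order, , drop = FALSE]
  rad <- radius[order]
  par <- comps$parent
  len <- numeric(n); pd <- numeric(n)
  for (i in seq_len(n)) {
    if (is.na(par[i])) {
      len[i] <- 2 * rad[i]   # soma sample: sphere treated as cylinder
      pd[i] <- 0
    } else {
      seg <- sqrt(sum((xyz[i, ] - xyz[par[i], ]) ^ 2))
      if (seg <= 0) seg <- 2 * rad[i]
      len[i] <- seg
      pd[i] <- pd[par[i]] + seg
    }
  }
  comps$length <- len
  comps$path_distance <- pd
  comps$area <- pi * comps$diameter * comps$length

  structure(
    list(
      compartments = comps,
      sites = c(S = 1L),
      axial_resistivity = axial_resistivity,
      capacitance = capacitance
    ),
    class = "ivl_morphology"
  )
}

#' @export
print.ivl_morphology <- function(x, ...) {
  cm <- x$compartments
  cat("<ivl_morphology> ", nrow(cm), " compartments (",
      sum(cm$region == "soma"), " soma, ",
      sum(cm$region == "dend"), " dend, ",
      sum(cm$region == "axon"), " axon); total area ",
      format(round(sum(cm$area), 1)), " um^2\n", sep = "")
  cat("sites:", paste(names(x$sites), "=", x$sites, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a morphology into its compartment table
#' @param x An `ivl_morphology`.
#' @param ... Unused.
#' @return The compartment tibble.
#' @export
tidy.ivl_morphology <- function(x, ...) x$compartments

# axial coupling conductance (uS) between each compartment and its parent
axial_conductance <- function(morph) {
  cm <- morph$compartments
  ra <- morph$axial_resistivity * 1e4   # ohm cm -> ohm um
  half_r <- ra * (cm$length / 2) / (pi * (cm$diameter / 2) ^ 2)  # ohm
  g <- numeric(nrow(cm))
  for (i in seq_len(nrow(cm))) {
    p <- cm$parent[i]
    if (!is.na(p)) g[i] <- 1e6 / (half_r[i] + half_r[p])  # uS
  }
  g
}

# membrane capacitance (nF) per compartment: 1 uF/cm^2 over 1 um^2 = 1e-5 nF
membrane_capacitance <- function(morph) {
  morph$capacitance * morph$compartments$area * 1e-5
}
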