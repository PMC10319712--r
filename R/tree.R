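#' Arterial tree topology and bookkeeping
#'
#' The reduced distributed model represents each artery as a tapered
#' elastic tube discretized into lumped elements (Poiseuille resistance
#' 8 pi mu l / A^2, inertance rho l / A, volume compliance c = D A l),
#' terminated by three-element Windkessels at the peripheral beds. The
#' tree ships as a plain-text table of segments; per-subject variants are
#' produced by uniform geometric and distensibility scaling
#' ([build_scaled_tree()]).
#'
#' @param path segment table (CSV with columns id, name, parent,
#'   length_cm, prox_diam_cm, dist_diam_cm, distensibility_per_Pa,
#'   terminal). Defaults to the packaged 24-segment tree.
#' @param blood list with `density` (kg/m^3) and `viscosity` (Pa s).
#' @return An object of class `arterial_tree`.
#' @export
load_arterial_tree <- function(path = system.file("extdata", "arterial_tree_24.csv",
                                                  package = "dpdecay"),
                               blood = list(density = 1050, viscosity = 0.004)) {
  seg <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "name", "parent", "length_cm", "prox_diam_cm",
            "dist_diam_cm", "distensibility_per_Pa", "terminal")
  if (!all(need %in% names(seg))) stop_invalid("malformed tree file: ", path)
  if (any(seg$length_cm <= 0) || any(seg$prox_diam_cm <= 0) ||
      any(seg$dist_diam_cm <= 0) || any(seg$distensibility_per_Pa <= 0))
    stop_invalid("tree geometry must be strictly positive")
  check_positive(blood$density, "blood density")
  check_positive(blood$viscosity, "blood viscosity")
  root <- seg$id[is.na(seg$parent)]
  if (length(root) != 1) stop_invalid("tree must have exactly one root segment")
  # connectivity / acyclicity: every segment must reach the root
  for (i in seq_len(nrow(seg))) {
    cur <- seg$id[i]; hops <- 0
    while (!is.na(cur) && hops <= nrow(seg)) {
      cur <- seg$parent[match(cur, seg$id)]; hops <- hops + 1
    }
    if (hops > nrow(seg)) stop_invalid("tree contains a cycle")
  }
  structure(list(segments = seg, blood = blood, terminals = NULL,
                 targets = NULL,
                 config = list(terminal_compliance_fraction = 0.2,
                               resistance_exponent = 2)),
            class = "arterial_tree")
}

#' @export
print.arterial_tree <- function(x, ...) {
  cat(sprintf("<arterial_tree> %d segments (%d terminal), C_total = %.3f mL/mmHg%s\n",
              nrow(x$segments), sum(x$segments$terminal),
              tree_total_compliance(x),
              if (is.null(x$targets)) " [no vascular targets set]"
              else sprintf(", TPR target = %.3f mmHg s/mL", x$targets$tpr)))
  invisible(x)
}

# mean cross-sectional area per segment, m^2
segment_area_m2 <- function(seg) {
  d_mean_m <- (seg$prox_diam_cm + seg$dist_diam_cm) / 2 / 100
  pi / 4 * d_mean_m^2
}

#' Segment volume compliances
#'
#' c_i = D * A * l per segment, converted to mL/mmHg.
#' @param tree an [load_arterial_tree()] object.
#' @return numeric vector, one entry per segment.
#' @export
segment_compliances <- function(tree) {
  seg <- tree$segments
  si_to_ml_mmhg(seg$distensibility_per_Pa * segment_area_m2(seg) *
                  (seg$length_cm / 100))
}

#' Analytic total arterial compliance
#'
#' Sum of segment volume compliances plus terminal compliances (if
#' terminals have been built). Pure bookkeeping, never fitted.
#' @param tree an `arterial_tree`.
#' @return total compliance (mL/mmHg).
#' @export
tree_total_compliance <- function(tree) {
  ct <- if (is.null(tree$terminals)) 0 else sum(tree$terminals$compliance)
  sum(segment_compliances(tree)) + ct
}

#' Local pulse wave velocity from wall distensibility
#'
#' Bramwell-Hill form pwv = 1 / sqrt(rho * D).
#' @param distensibility wall distensibility D (1/Pa).
#' @param density blood density (kg/m^3).
#' @return wave speed (m/s).
#' @export
compute_local_pwv <- function(distensibility, density = 1050) {
  check_positive(distensibility, "distensibility")
  check_positive(density, "density")
  1 / sqrt(density * distensibility)
}

#' Characteristic impedance of an arterial cross-section
#'
#' Z_c = rho * pwv / A, converted to mmHg s/mL.
#' @param diameter_cm lumen diameter (cm).
#' @param pwv local pulse wave velocity (m/s).
#' @param density blood density (kg/m^3).
#' @return impedance (mmHg s/mL).
#' @export
compute_characteristic_impedance <- function(diameter_cm, pwv, density = 1050) {
  check_positive(diameter_cm, "diameter")
  check_positive(pwv, "pwv")
  check_positive(density, "density")
  area_m2 <- pi / 4 * (diameter_cm / 100)^2
  si_to_mmhg_s_ml(density * pwv / area_m2)
}

#' Set per-subject vascular targets on a tree
#'
#' Rescales all distensibilities by one solved factor so that the
#' analytic total compliance equals `total_compliance` (a configurable
#' fraction of which is pooled into the terminal Windkessels), and builds
#' the terminal table so that the parallel total resistance seen from the
#' aortic root (path viscous resistance + terminal elements) equals
#' `tpr`.
#'
#' @param tree an `arterial_tree` (geometry already scaled if needed).
#' @param total_compliance target total arterial compliance (mL/mmHg).
#' @param tpr target total peripheral resistance (mmHg s/mL).
#' @return The tree with terminals and targets attached.
#' @export
set_vascular_targets <- function(tree, total_compliance, tpr) {
  check_positive(total_compliance, "total_compliance")
  check_positive(tpr, "tpr")
  frac <- tree$config$terminal_compliance_fraction
  # segments carry (1 - frac) of total C: solve one multiplicative factor
  c_now <- sum(segment_compliances(tree))
  tree$segments$distensibility_per_Pa <-
    tree$segments$distensibility_per_Pa * (1 - frac) * total_compliance / c_now

  seg <- tree$segments
  term <- seg[seg$terminal == 1, ]
  a_out <- pi / 4 * (term$dist_diam_cm / 100)^2          # outlet area m^2
  g <- a_out^tree$config$resistance_exponent
  share <- g / sum(g)                                    # conductance share
  r_total <- tpr / share                                 # parallel total = tpr

  pwv_out <- 1 / sqrt(tree$blood$density * term$distensibility_per_Pa)
  z <- si_to_mmhg_s_ml(tree$blood$density * pwv_out / a_out)
  path_r <- terminal_path_resistance(tree, term$id)
  # in very stiff / small-caliber subjects the characteristic impedance
  # can approach a bed's resistance share; cap it so the three-element
  # terminal stays solvable with a positive distal resistance
  z <- pmin(z, 0.5 * (r_total - path_r))
  r_dist <- r_total - z - path_r
  if (any(r_dist <= 0))
    stop_invalid("unsolvable terminal resistances: the viscous path ",
                 "resistance alone exceeds a terminal's share of TPR")
  tree$terminals <- data.frame(
    segment_id = term$id, name = term$name,
    proximal_resistance = z, distal_resistance = r_dist,
    compliance = frac * total_compliance * share)
  tree$targets <- list(total_compliance = total_compliance, tpr = tpr)
  tree
}

# Series Poiseuille resistance accumulated from the root to each terminal
# segment's distal end (mmHg s/mL).
terminal_path_resistance <- function(tree, term_ids) {
  seg <- tree$segments
  mu <- tree$blood$viscosity
  r_seg <- si_to_mmhg_s_ml(8 * pi * mu * (seg$length_cm / 100) /
                             segment_area_m2(seg)^2)
  vapply(term_ids, function(id) {
    total <- 0; cur <- id
    while (!is.na(cur)) {
      i <- match(cur, seg$id)
      total <- total + r_seg[i]
      cur <- seg$parent[i]
    }
    total
  }, numeric(1))
}

#' Build a subject-specific tree from a parameter draw
#'
#' Applies the uniform geometric scalings (all diameters by
#' `inlet_diameter / reference inlet diameter`, all lengths by
#' `height / 180`) and then solves the distensibility and terminal
#' scalings to hit the subject's sampled total compliance and TPR.
#'
#' @param reference_tree the reference `arterial_tree` (180 cm subject).
#' @param draw a list/row with `inlet_diameter` (cm), `height` (cm),
#'   `total_arterial_compliance` (mL/mmHg), `total_peripheral_resistance`
#'   (mmHg s/mL).
#' @return A scaled `arterial_tree` with terminals built.
#' @export
build_scaled_tree <- function(reference_tree, draw) {
  for (f in c("inlet_diameter", "height", "total_arterial_compliance",
              "total_peripheral_resistance"))
    check_positive(draw[[f]], f)
  tree <- reference_tree
  ref_inlet <- tree$segments$prox_diam_cm[is.na(tree$segments$parent)]
  dscale <- draw$inlet_diameter / ref_inlet
  lscale <- draw$height / 180
  tree$segments$prox_diam_cm <- tree$segments$prox_diam_cm * dscale
  tree$segments$dist_diam_cm <- tree$segments$dist_diam_cm * dscale
  tree$segments$length_cm <- tree$segments$length_cm * lscale
  tree$scaling <- list(diameter_scale = dscale, length_scale = lscale)
  set_vascular_targets(tree, draw$total_arterial_compliance,
                       draw$total_peripheral_resistance)
}

# Discretize the tree into the lumped network consumed by the C++
# integrator. Each segment becomes >= min_elements RLC elements of target
# length elem_len_cm; element compliance goes to its distal node, except
# the root segment's first element whose compliance is split with the
# aortic-root node so the heart sees a compliant node.
discretize_tree <- function(tree, elem_len_cm = 2.5, min_elements = 4) {
  if (is.null(tree$terminals))
    stop_invalid("tree has no terminals; call set_vascular_targets() first")
  seg <- tree$segments
  rho <- tree$blood$density; mu <- tree$blood$viscosity
  node_C <- numeric(0); br <- list(); seg_end_node <- integer(nrow(seg))
  # node 1 (R indexing) = aortic root
  node_C[1] <- 0
  next_node <- 1L
  order_idx <- order(ifelse(is.na(seg$parent), 0, 1), seg$id) # root first
  for (i in order_idx) {
    s <- seg[i, ]
    k <- max(min_elements, ceiling(s$length_cm / elem_len_cm))
    le <- s$length_cm / k / 100                     # element length, m
    # linear taper: element mid diameters
    dm <- s$prox_diam_cm + (s$dist_diam_cm - s$prox_diam_cm) *
      ((seq_len(k) - 0.5) / k)
    A <- pi / 4 * (dm / 100)^2
    Re <- si_to_mmhg_s_ml(8 * pi * mu * le / A^2)
    Le <- si_to_mmhg_s_ml(rho * le / A) * 1  # Pa s^2/m^3 -> mmHg s^2/mL
    ce <- si_to_ml_mmhg(s$distensibility_per_Pa * A * le)
    upstream <- if (is.na(s$parent)) 1L else seg_end_node[match(s$parent, seg$id)]
    for (j in seq_len(k)) {
      next_node <- next_node + 1L
      node_C[next_node] <- ce[j]
      if (is.na(s$parent) && j == 1L) {             # split with root node
        node_C[1] <- node_C[1] + ce[1] / 2
        node_C[next_node] <- ce[1] / 2
      }
      br[[length(br) + 1]] <- c(upstream, next_node, Re[j], Le[j])
      upstream <- next_node
    }
    seg_end_node[i] <- upstream
  }
  brm <- do.call(rbind, br)
  term <- tree$terminals
  term_node <- seg_end_node[match(term$segment_id, seg$id)]
  # branch index feeding each named segment's distal node (for flow record)
  end_branch <- vapply(seq_len(nrow(seg)),
                       function(i) which(brm[, 2] == seg_end_node[i])[1],
                       numeric(1))
  list(node_C = node_C,
       br_from = as.integer(brm[, 1]), br_to = as.integer(brm[, 2]),
       br_R = brm[, 3], br_L = brm[, 4],
       term_node = as.integer(term_node),
       term_Z = term$proximal_resistance,
       term_R = term$distal_resistance,
       term_C = term$compliance,
       seg_end_node = seg_end_node, seg_end_branch = as.integer(end_branch),
       root_node = 1L, n_nodes = length(node_C))
}
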