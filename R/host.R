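#' @useDynLib pleionet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rbinom setNames coef glm quasibinomial binomial
#'   pnorm cor var
#' @importFrom utils write.csv read.csv head
NULL

PROTEIN_ROLES <- c("detector", "signal", "effector")
NETWORKS <- c("immune", "developmental", "shared")

#' Networks a protein belongs to
#'
#' A shared effector is a member of both the immune and the developmental
#' network; every other protein belongs to exactly one.
#'
#' @param network the protein's network tag.
#' @return character vector of network names.
#' @keywords internal
protein_networks <- function(network) {
  if (network == "shared") c("immune", "developmental") else network
}

new_host <- function(architecture, proteins, edges) {
  h <- structure(
    list(architecture = architecture, proteins = proteins, edges = edges,
         cache = NULL),
    class = "pleio_host")
  h$cache <- build_host_cache(h)
  h
}

#' Create a random founder host
#'
#' Builds the starting protein roster for the chosen architecture and wires
#' it at random: every valid ordered pair of same-network proteins receives a
#' regulatory edge with probability 0.5, its coefficient drawn uniformly on
#' \eqn{[-1, 1]}. Positive coefficients upregulate the target, negative ones
#' downregulate it. Detectors and effectors never connect directly, and only
#' signalling proteins may carry self-loops. No cross-network edges exist at
#' initialization (the shared effector belongs to both networks, so its
#' connections to either network's proteins are within-network).
#'
#' @param architecture `"independent"` (a detector, three signalling proteins
#'   and an effector per network: 10 proteins) or `"shared"` (the two
#'   networks share a single effector: 9 proteins).
#' @param edge_prob probability that a valid connection is realized
#'   (default 0.5).
#' @return a `pleio_host`: architecture tag, protein roster
#'   (`data.frame(id, role, network)`), signed edge list
#'   (`data.frame(source, target, coefficient)`).
#' @examples
#' set.seed(1)
#' h <- init_host("shared")
#' nrow(h$proteins)  # 9
#' @export
init_host <- function(architecture = c("independent", "shared"),
                      edge_prob = 0.5) {
  architecture <- match.arg(architecture)
  proteins <- founder_roster(architecture)
  pairs <- valid_init_pairs(proteins)
  keep <- runif(nrow(pairs)) < edge_prob
  edges <- data.frame(source = pairs$source[keep], target = pairs$target[keep],
                      coefficient = runif(sum(keep), -1, 1))
  new_host(architecture, proteins, edges)
}

founder_roster <- function(architecture) {
  if (architecture == "independent") {
    data.frame(
      id = 1:10,
      role = c("detector", "signal", "signal", "signal", "effector",
               "detector", "signal", "signal", "signal", "effector"),
      network = rep(c("immune", "developmental"), each = 5))
  } else {
    data.frame(
      id = 1:9,
      role = c("detector", "signal", "signal", "signal",
               "detector", "signal", "signal", "signal", "effector"),
      network = c(rep("immune", 4), rep("developmental", 4), "shared"))
  }
}

#' Enumerate the valid initial connections of a protein roster
#'
#' An ordered pair (source, target) is a valid initial connection when both
#' proteins share a network, the pair is not a detector-effector pair in
#' either order, and source equals target only for signalling proteins.
#' This enumeration also serves as the denominator of network connectivity.
#'
#' @param proteins a host protein roster (`data.frame(id, role, network)`).
#' @return `data.frame(source, target)` of valid ordered pairs.
#' @export
valid_init_pairs <- function(proteins) {
  n <- nrow(proteins)
  src <- rep(seq_len(n), each = n)
  tgt <- rep(seq_len(n), times = n)
  role_s <- proteins$role[src]
  role_t <- proteins$role[tgt]
  same_net <- mapply(function(a, b) {
    length(intersect(protein_networks(a), protein_networks(b))) > 0L
  }, proteins$network[src], proteins$network[tgt])
  det_eff <- (role_s == "detector" & role_t == "effector") |
             (role_s == "effector" & role_t == "detector")
  self_ok <- src != tgt | (role_s == "signal")
  ok <- same_net & !det_eff & self_ok
  data.frame(source = proteins$id[src][ok], target = proteins$id[tgt][ok])
}

#' Is a single edge legal for this host?
#'
#' Mutation may wire any ordered pair of proteins, cross-network included;
#' the only restrictions are that detectors and effectors never connect
#' directly and that self-loops are reserved for signalling proteins.
#'
#' @param host a `pleio_host`.
#' @param source,target protein ids.
#' @return logical scalar.
#' @export
legal_edge <- function(host, source, target) {
  p <- host$proteins
  rs <- p$role[match(source, p$id)]
  rt <- p$role[match(target, p$id)]
  if (is.na(rs) || is.na(rt)) return(FALSE)
  if ((rs == "detector" && rt == "effector") ||
      (rs == "effector" && rt == "detector")) return(FALSE)
  if (source == target && rs != "signal") return(FALSE)
  TRUE
}

#' Validate a host genotype
#'
#' Checks the structural invariants maintained by mutation: detector and
#' effector rosters fixed by architecture, at least one signalling protein
#' per network, all edges legal with coefficients in \eqn{[-1, 1]}, and no
#' duplicate ordered pairs.
#'
#' @param host a `pleio_host`.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_host <- function(host) {
  p <- host$proteins
  e <- host$edges
  if (anyDuplicated(p$id)) stop("duplicate protein ids")
  det <- p[p$role == "detector", ]
  eff <- p[p$role == "effector", ]
  if (nrow(det) != 2L) stop("host must carry exactly two detectors")
  n_eff <- if (host$architecture == "independent") 2L else 1L
  if (nrow(eff) != n_eff) stop("wrong effector count for architecture")
  if (host$architecture == "shared" && eff$network != "shared")
    stop("shared-architecture effector must belong to both networks")
  for (net in c("immune", "developmental")) {
    sig <- sum(p$role == "signal" & p$network == net)
    if (sig < 1L) stop("network '", net, "' lost its last signalling protein")
  }
  if (nrow(e)) {
    if (any(is.na(match(e$source, p$id))) || any(is.na(match(e$target, p$id))))
      stop("edge references a missing protein id")
    if (any(abs(e$coefficient) > 1)) stop("coefficient outside [-1, 1]")
    ok <- mapply(legal_edge, e$source, e$target,
                 MoreArgs = list(host = host))
    if (!all(ok)) stop("illegal edge (detector-effector or non-signal self-loop)")
    if (anyDuplicated(paste(e$source, e$target))) stop("duplicate edge")
  }
  invisible(TRUE)
}

# Precompute the dense operators the dynamics kernel consumes: node order is
# protein id order; K holds upregulatory coefficients (K[i, j] = action of j
# on i), I the magnitudes of downregulatory ones; out_deg counts outgoing
# interactions per node for the protein-use term.
build_host_cache <- function(host) {
  p <- host$proteins[order(host$proteins$id), ]
  n <- nrow(p)
  K <- matrix(0, n, n)
  Imat <- matrix(0, n, n)
  out_deg <- integer(n)
  e <- host$edges
  if (nrow(e)) {
    si <- match(e$source, p$id)
    ti <- match(e$target, p$id)
    for (r in seq_len(nrow(e))) {
      cf <- e$coefficient[r]
      if (cf >= 0) K[ti[r], si[r]] <- K[ti[r], si[r]] + cf
      else Imat[ti[r], si[r]] <- Imat[ti[r], si[r]] - cf
    }
    tab <- tabulate(si, nbins = n)
    out_deg <- tab
  }
  imm_sig <- p$id[p$role == "signal" & p$network == "immune"]
  list(
    ids = p$id,
    roles = p$role,
    K = K, I = Imat, out_deg = out_deg,
    idx_immune_detector = which(p$role == "detector" & p$network == "immune"),
    idx_dev_detector = which(p$role == "detector" &
                               p$network == "developmental"),
    idx_immune_effector = which(p$role == "effector" &
                                  p$network %in% c("immune", "shared")),
    idx_dev_effector = which(p$role == "effector" &
                               p$network %in% c("developmental", "shared")),
    idx_immune_signals = match(sort(imm_sig), p$id)
  )
}

refresh_cache <- function(host) {
  host$cache <- build_host_cache(host)
  host
}

#' Create a random founder parasite
#'
#' A parasite genotype is a target index over host immune signalling
#' proteins (resolved per host by modulo), a regulatory coefficient on that
#' target drawn uniformly on \eqn{[-1, 1]}, a fixed self-targeted
#' upregulatory action of 0.8 representing within-host replication, and a
#' fixed +1 upregulatory connection to the host immune detector.
#'
#' @param cfg a `sim_config` supplying the fixed coefficients and the target
#'   index domain.
#' @return a `pleio_parasite`.
#' @export
init_parasite <- function(cfg = sim_config()) {
  structure(
    list(target_index = sample.int(cfg$parasite_target_domain, 1L) - 1L,
         target_coefficient = runif(1, -1, 1),
         self_coefficient = cfg$parasite_self_coef,
         detector_coefficient = cfg$parasite_detector_coef),
    class = "pleio_parasite")
}

#' @export
print.pleio_host <- function(x, ...) {
  cat(sprintf("<pleio_host> %s-effector: %d proteins, %d edges\n",
              x$architecture, nrow(x$proteins), nrow(x$edges)))
  tab <- table(x$proteins$network, x$proteins$role)
  print(tab)
  invisible(x)
}

#' @export
print.pleio_parasite <- function(x, ...) {
  cat(sprintf(
    "<pleio_parasite> target index %d (coefficient %+.3f), self +%.2f, detector +%.1f\n",
    x$target_index, x$target_coefficient, x$self_coefficient,
    x$detector_coefficient))
  invisible(x)
}

# Stable structural key for a genotype: architecture, sorted roster, sorted
# edges at full precision. Used for modal-genotype counting and table keys.
canonical_genotype_string <- function(host) {
  p <- host$proteins[order(host$proteins$id), ]
  e <- host$edges
  if (nrow(e)) e <- e[order(e$source, e$target), ]
  paste(
    host$architecture,
    paste(p$id, p$role, p$network, sep = ":", collapse = ";"),
    paste(e$source, e$target, sprintf("%.17g", e$coefficient),
          sep = ":", collapse = ";"),
    sep = "|")
}

#' Stable digest of a host genotype
#'
#' 32-bit FNV-1a hash of the canonicalized roster and edge list; identical
#' genotypes (same architecture, proteins and coefficients) share a hash.
#'
#' @param host a `pleio_host`.
#' @return an 8-character hexadecimal string.
#' @export
genotype_hash <- function(host) {
  bytes <- utf8ToInt(canonical_genotype_string(host))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply in 16-bit halves to stay within double precision
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * prime + (hi * prime %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", (h - h %% 65536) / 65536), sprintf("%04x", h %% 65536))
}
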