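# Genotype algebra for the three-node network.
#
# A genotype assigns to each node (sensor, regulator, output) either the
# wild-type allele (coded 0) or a mutant allele index 1..M. Its "order" is
# the number of mutated nodes. The canonical string form joins mutated
# nodes in the fixed node order with "+", e.g. "sensor-3+output-7"; the
# unmutated network is "WT". These strings are the join keys used in every
# table the pipeline emits.

#' Canonical node identifiers
#'
#' The three nodes of the network in their fixed canonical order: the
#' sensor (activated by the inducer, represses the other two nodes), the
#' regulator (represses the output) and the output (the fluorescent
#' reporter).
#'
#' @return Character vector `c("sensor", "regulator", "output")`.
#' @export
nodes <- function() c("sensor", "regulator", "output")

#' Build a canonical genotype string
#'
#' @param sensor,regulator,output Allele at each node: 0 for wild type or a
#'   mutant index >= 1.
#' @return Canonical genotype string, `"WT"` when all alleles are 0.
#' @examples
#' genotype_string(3, 0, 7) # "sensor-3+output-7"
#' @export
genotype_string <- function(sensor = 0L, regulator = 0L, output = 0L) {
  alleles <- cbind(sensor, regulator, output)
  if (any(alleles < 0 | alleles != floor(alleles))) {
    stop("alleles must be non-negative integers (0 = wild type)")
  }
  apply(alleles, 1L, function(a) {
    mut <- which(a > 0)
    if (length(mut) == 0L) return("WT")
    paste(paste0(nodes()[mut], "-", a[mut]), collapse = "+")
  })
}

#' Parse a canonical genotype string
#'
#' @param genotype Character vector of canonical genotype strings.
#' @return A tibble with integer columns `sensor`, `regulator`, `output`
#'   (0 = wild-type allele), the input `genotype` and its `order`.
#' @export
parse_genotype <- function(genotype) {
  out <- tibble::tibble(genotype = as.character(genotype),
                        sensor = 0L, regulator = 0L, output = 0L)
  for (i in seq_along(out$genotype)) {
    g <- out$genotype[i]
    if (identical(g, "WT")) next
    parts <- strsplit(g, "+", fixed = TRUE)[[1]]
    m <- regmatches(parts, regexec("^(sensor|regulator|output)-([0-9]+)$", parts))
    if (any(lengths(m) != 3L)) stop("malformed genotype string: ", g)
    for (p in m) {
      if (out[[p[2]]][i] != 0L) stop("duplicate node in genotype string: ", g)
      out[[p[2]]][i] <- as.integer(p[3])
    }
  }
  out$order <- genotype_order(out)
  out[, c("genotype", "sensor", "regulator", "output", "order")]
}

#' Mutational order of genotypes
#'
#' @param genotypes A data frame with allele columns `sensor`, `regulator`,
#'   `output` (0 = wild type).
#' @return Integer vector: the number of mutated nodes (0 to 3).
#' @export
genotype_order <- function(genotypes) {
  as.integer((genotypes$sensor > 0) + (genotypes$regulator > 0) +
               (genotypes$output > 0))
}

#' Enumerate all genotypes up to triplet combinations
#'
#' Generates the wild type, all `3 * M` single mutants, all `3 * M^2`
#' pairwise combinations (one node left wild type) and all `M^3` triplet
#' combinations, where `M` is the number of mutant alleles available per
#' node.
#'
#' @param mutants_per_node Number of mutant alleles per node (`M >= 1`);
#'   default 10, giving 300 pairwise and 1000 triplet combinations.
#' @return A tibble with columns `genotype`, `sensor`, `regulator`,
#'   `output`, `order`, one row per unique genotype.
#' @examples
#' nrow(enumerate_genotypes(1)) # 8
#' @export
enumerate_genotypes <- function(mutants_per_node = 10L) {
  M <- mutants_per_node
  if (length(M) != 1L || is.na(M) || M < 1 || M != floor(M)) {
    stop("mutants_per_node must be a single integer >= 1")
  }
  M <- as.integer(M)
  grid <- expand.grid(sensor = 0:M, regulator = 0:M, output = 0:M,
                      KEEP.OUT.ATTRS = FALSE)
  out <- tibble::tibble(
    sensor = as.integer(grid$sensor),
    regulator = as.integer(grid$regulator),
    output = as.integer(grid$output)
  )
  out$order <- genotype_order(out)
  out$genotype <- genotype_string(out$sensor, out$regulator, out$output)
  out <- out[order(out$order, out$sensor, out$regulator, out$output), ]
  tibble::as_tibble(out[, c("genotype", "sensor", "regulator", "output", "order")])
}

#' Combinations containing a given single mutant
#'
#' All pairwise or triplet genotypes whose allele at the focal node equals
#' the focal single mutant's allele. At `M` mutants per node a single
#' mutant appears in `2 * M` pairwise and `M^2` triplet combinations.
#'
#' @param genotype Canonical string of a single-mutant genotype, e.g.
#'   `"sensor-1"`.
#' @param order 2 for pairwise or 3 for triplet combinations.
#' @param mutants_per_node Number of mutant alleles per node.
#' @return Tibble of genotypes (same shape as [enumerate_genotypes()]).
#' @export
combinations_containing <- function(genotype, order, mutants_per_node = 10L) {
  g <- parse_genotype(genotype)
  if (nrow(g) != 1L || g$order != 1L) {
    stop("genotype must be a single-mutant genotype")
  }
  if (!order %in% c(2L, 3L)) stop("order must be 2 or 3")
  all_g <- enumerate_genotypes(mutants_per_node)
  node <- nodes()[which(c(g$sensor, g$regulator, g$output) > 0)]
  allele <- max(g$sensor, g$regulator, g$output)
  if (allele > mutants_per_node) {
    stop("allele index exceeds mutants_per_node")
  }
  all_g[all_g$order == order & all_g[[node]] == allele, ]
}

#' Constituent single mutants of a combination
#'
#' @param genotype Canonical genotype string of order >= 1.
#' @return Character vector of the canonical single-mutant genotype strings
#'   making up the combination (length = order).
#' @export
constituent_singles <- function(genotype) {
  g <- parse_genotype(genotype)
  if (nrow(g) != 1L) stop("one genotype at a time")
  if (g$order < 1L) stop("WT has no constituent mutants")
  alleles <- c(sensor = g$sensor, regulator = g$regulator, output = g$output)
  unname(vapply(which(alleles > 0), function(i) {
    a <- c(0L, 0L, 0L); a[i] <- alleles[[i]]
    genotype_string(a[1], a[2], a[3])
  }, character(1)))
}
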