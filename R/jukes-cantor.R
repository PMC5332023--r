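#' Expected p-distance under the Jukes-Cantor model
#'
#' Closed-form link between an expected number of substitutions per site
#' \code{d} and the expected uncorrected p-distance,
#' \deqn{p = \frac{3}{4}\left(1 - e^{-4d/3}\right).}
#' Used to calibrate simulated alignments so that their expected pairwise
#' distances hit target values on the p-distance scale.
#'
#' @param d Expected substitutions per site, non-negative (vectorized).
#' @return Expected p-distance in \code{[0, 0.75)}; strictly increasing
#'   in \code{d}.
#' @examples
#' jcExpectedP(0)        # 0
#' jcExpectedP(0.1073)   # ~0.10
#' @seealso [jcDivergence()] for the inverse.
#' @export
jcExpectedP <- function(d) {
  if (any(!is.finite(d)) || any(d < 0))
    stop("divergence d must be finite and non-negative")
  0.75 * (1 - exp(-4 * d / 3))
}

#' Invert the Jukes-Cantor p-distance link
#'
#' @param p Expected p-distance in \code{[0, 0.75)}.
#' @return The divergence \code{d} (substitutions/site) with
#'   \code{jcExpectedP(d) == p}.
#' @examples
#' jcDivergence(0.10)  # ~0.1073
#' @export
jcDivergence <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p >= 0.75))
    stop("p must lie in [0, 0.75)")
  -0.75 * log(1 - 4 * p / 3)
}

# Evolve sequences one step under Jukes-Cantor: each site substitutes with
# probability jcExpectedP(d), and a substituted site takes one of the three
# other bases uniformly.  This is exactly the JC transition kernel at
# divergence d, so kernels compose additively along a path.
.jcEvolve <- function(seqMat, d) {
  if (d == 0) return(seqMat)
  bases <- c("A", "C", "G", "T")
  p <- jcExpectedP(d)
  hit <- matrix(stats::runif(length(seqMat)) < p, nrow = nrow(seqMat))
  n <- sum(hit)
  if (n > 0) {
    # draw a uniform base distinct from the current one
    shift <- sample.int(3L, n, replace = TRUE)
    cur <- match(seqMat[hit], bases)
    seqMat[hit] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  }
  seqMat
}

#' Specify one simulated clade
#'
#' One row of the simulation request consumed by [simulateAlignment()]:
#' a named lineage with \code{nTips} tip sequences, whose ancestor sits
#' \code{stemDivergence} expected substitutions/site from the root and
#' whose tips each sit \code{tipDivergence} from the clade ancestor
#' (star topology within and between clades).
#'
#' @param label Clade label (unique within a request).
#' @param nTips Number of tip sequences, >= 1.
#' @param stemDivergence Expected substitutions/site, root to clade
#'   ancestor, >= 0.
#' @param tipDivergence Expected substitutions/site, clade ancestor to
#'   each tip, >= 0.
#' @return One-row data.frame; rbind rows to build a request.
#' @examples
#' rbind(cladeSimSpec("A", 3, 0.05, 0.002),
#'       cladeSimSpec("B", 4, 0.06, 0.001))
#' @export
cladeSimSpec <- function(label, nTips, stemDivergence, tipDivergence) {
  stopifnot(length(label) == 1L, nTips >= 1)
  if (!is.finite(stemDivergence) || stemDivergence < 0 ||
      !is.finite(tipDivergence) || tipDivergence < 0)
    stop("stemDivergence and tipDivergence must be finite and non-negative")
  data.frame(label = as.character(label), nTips = as.integer(nTips),
             stemDivergence = stemDivergence, tipDivergence = tipDivergence,
             stringsAsFactors = FALSE)
}

#' Simulate a clade-structured alignment under Jukes-Cantor
#'
#' Draws a uniform random root sequence, evolves one ancestor per clade
#' down its stem, then evolves each tip from its clade ancestor.  The
#' expected p-distance between tips of clades i and j is
#' \code{jcExpectedP(stem_i + stem_j + tip_i + tip_j)}, and within clade i
#' it is \code{jcExpectedP(2 * tip_i)}, which lets simulations be
#' calibrated analytically to target distance tables.
#'
#' @param specs data.frame of clade specifications (rbind of
#'   [cladeSimSpec()] rows).
#' @param seqLength Number of sites, >= 100.
#' @param seed Integer seed; the simulation is deterministic given it.
#' @return A list with \code{alignment} (a
#'   [Biostrings::DNAStringSet-class], ids \code{<label>_<k>}) and
#'   \code{clades} (named character vector mapping id to clade label).
#' @examples
#' specs <- rbind(cladeSimSpec("A", 2, 0.055, 0), cladeSimSpec("B", 2, 0.055, 0))
#' sim <- simulateAlignment(specs, 1000, seed = 1)
#' sim$alignment
#' @export
simulateAlignment <- function(specs, seqLength, seed) {
  if (!is.data.frame(specs) || nrow(specs) < 1L)
    stop("specs must contain at least one clade specification")
  if (anyDuplicated(specs$label))
    stop("clade labels must be unique")
  if (seqLength < 100) stop("seqLength must be at least 100")
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  root <- matrix(sample(bases, seqLength, replace = TRUE), nrow = 1L)
  seqs <- character(0)
  clades <- character(0)
  for (i in seq_len(nrow(specs))) {
    anc <- .jcEvolve(root, specs$stemDivergence[i])
    for (k in seq_len(specs$nTips[i])) {
      tip <- .jcEvolve(anc, specs$tipDivergence[i])
      id <- sprintf("%s_%d", specs$label[i], k)
      seqs[id] <- paste(tip, collapse = "")
      clades[id] <- specs$label[i]
    }
  }
  list(alignment = Biostrings::DNAStringSet(seqs), clades = clades)
}

#' Draw snout-vent length samples
#'
#' i.i.d. normal draws emulating per-clade male SVL samples (mm).
#'
#' @param mean Mean SVL in mm.
#' @param sd Standard deviation in mm, >= 0.
#' @param n Sample size, >= 1.
#' @param seed Integer seed; draws are deterministic given it.
#' @return Numeric vector of length \code{n}.
#' @examples
#' sampleSvl(23.8, 1.5, 5, seed = 1)
#' @export
sampleSvl <- function(mean, sd, n, seed) {
  if (n < 1) stop("n must be at least 1")
  if (sd < 0) stop("sd must be non-negative")
  set.seed(as.integer(seed))
  stats::rnorm(n, mean = mean, sd = sd)
}
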