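## Synthetic survival-image benchmark generators. Two designs are
## emulated: (i) two visually distinct image classes whose survival times
## are exponential with class-constant hazards exp(phi_j) on a unit
## baseline, with optional median-based censoring; (ii) nodule-style
## images where every sample carries small benign dots and the cancer
## group additionally carries two white patches whose size drives a
## size-proportional log relative hazard, with two-level censoring.
## Every stage draws from a substream derived deterministically from the
## master seed, so a spec reproduces its data exactly.

#' Construct a SimulationSpec
#'
#' @param classLogHazards per-class log relative hazards \eqn{\phi_j}.
#'   The default `c(0, 3)` gives a theoretical best-achievable
#'   concordance index of about 0.726 at class balance (see
#'   [theoreticalCIndex()]).
#' @param baselineRate constant baseline hazard; 1 reproduces the
#'   reference setting (times exponential with rate \eqn{e^{\phi_j}}).
#' @param censoringScheme `"none"`, `"median_half"` or `"nodule"`.
#' @param nTrain,nTest sample sizes.
#' @param seed integer master seed; all per-stage substreams derive from
#'   it.
#' @return a [SimulationSpec-class].
#' @export
simulationSpec <- function(classLogHazards = c(0, 3), baselineRate = 1,
                           censoringScheme = c("none", "median_half",
                                               "nodule"),
                           nTrain = 10000L, nTest = 1000L, seed = 1L) {
  new("SimulationSpec", classLogHazards = as.numeric(classLogHazards),
      baselineRate = as.numeric(baselineRate),
      censoringScheme = match.arg(censoringScheme),
      nTrain = as.integer(nTrain), nTest = as.integer(nTest),
      seed = as.integer(seed))
}

#' @export
setMethod("show", "SimulationSpec", function(object) {
  cat("SimulationSpec:", length(object@classLogHazards), "classes, phi = (",
      paste(format(object@classLogHazards), collapse = ", "),
      "), baseline rate", object@baselineRate, "\n")
  cat("  censoring:", object@censoringScheme, "; n =", object@nTrain,
      "train /", object@nTest, "test; seed", object@seed, "\n")
})

## Deterministic substream seed below 2^31, one per generation stage.
deriveSeed <- function(seed, stage) {
  as.integer((abs(as.double(seed)) %% 65011 * 33013 + stage * 7919 + 17) %%
               2147483647)
}

#' Simulate exponential survival times with class-constant hazards
#'
#' Each time is drawn independently from
#' `Exponential(rate = baselineRate * exp(phi_class))`, reproducibly under
#' the spec's seed.
#'
#' @param spec a [SimulationSpec-class].
#' @param classAssignments 1-based class index per sample.
#' @return numeric vector of times.
#' @export
simulateSurvivalTimes <- function(spec, classAssignments) {
  stopifnot(is(spec, "SimulationSpec"))
  cls <- as.integer(classAssignments)
  if (anyNA(cls) || any(cls < 1L) || any(cls > length(spec@classLogHazards)))
    stop("class assignment outside the spec's classes")
  set.seed(deriveSeed(spec@seed, 2L))
  rexp(length(cls), rate = spec@baselineRate * exp(spec@classLogHazards[cls]))
}

#' Median-based censoring within classes
#'
#' Among the records whose observed time lies strictly above the median
#' observed time of the whole cohort, exactly half (rounded down) are
#' selected uniformly at random -- independently within each class -- and
#' relabelled as censored; observed times are left unchanged. (With the
#' cohort median, the long-lived class loses many of its large event
#' times while the short-lived class is barely censored, which is what
#' makes the all-pairs concordance C1 exceed the event-only C2 in the
#' censored design; a per-class median would reverse that ordering.)
#' Classes with fewer than 2 records are left unmodified. All records
#' must currently be events.
#'
#' @param dataset a [SurvivalDataset-class] with all events.
#' @param classAssignments 1-based class per record.
#' @param seed integer seed for the random selection.
#' @return a new [SurvivalDataset-class].
#' @export
applyMedianCensoring <- function(dataset, classAssignments, seed) {
  stopifnot(is(dataset, "SurvivalDataset"))
  if (any(dataset@event != 1L))
    stop("median censoring expects an all-event dataset")
  cls <- as.integer(classAssignments)
  if (length(cls) != nSamples(dataset))
    stop("one class per record is required")
  set.seed(deriveSeed(seed, 4L))
  event <- dataset@event
  med <- median(dataset@time)
  for (k in sort(unique(cls))) {
    idx <- which(cls == k)
    if (length(idx) < 2L) next
    above <- idx[dataset@time[idx] > med]
    ncens <- floor(length(above) / 2)
    if (ncens > 0L)
      event[sample(above, ncens)] <- 0L
  }
  new("SurvivalDataset", time = dataset@time, event = event,
      label = dataset@label, sampleId = dataset@sampleId)
}

#' Two-class surrogate images
#'
#' Generates `nTrain + nTest` grayscale 28x28 images in two visually
#' distinct, linearly separable classes -- a ring and a bar, with random
#' jitter in position, size and intensity plus background pixel noise --
#' with balanced random class assignment. These stand in for a pair of
#' easily separable natural-image classes; the survival signal consumed by
#' the losses is carried entirely by the class identity.
#'
#' @param spec a [SimulationSpec-class] with exactly 2 classes.
#' @return an [ImageSet-class] with `classId` and `role`
#'   (`"train"`/`"test"`) filled in.
#' @export
makeTwoClassImages <- function(spec) {
  stopifnot(is(spec, "SimulationSpec"),
            length(spec@classLogHazards) == 2L)
  n <- spec@nTrain + spec@nTest
  if (spec@nTrain < 2L || spec@nTest < 2L)
    stop("need at least 2 training and 2 test samples")
  set.seed(deriveSeed(spec@seed, 1L))
  cls <- rbinom(n, 1L, 0.5) + 1L
  gx <- matrix(rep(1:28, each = 28), 28)   # column coordinate
  gy <- matrix(rep(1:28, times = 28), 28)  # row coordinate
  imgs <- array(0, dim = c(28L, 28L, 1L, n))
  for (i in seq_len(n)) {
    cx <- 14.5 + runif(1, -2, 2)
    cy <- 14.5 + runif(1, -2, 2)
    val <- runif(1, 0.6, 0.95)
    img <- matrix(runif(784, 0, 0.08), 28)
    if (cls[i] == 1L) {             # ring
      r <- runif(1, 6, 8)
      th <- runif(1, 0.8, 1.4)
      d <- sqrt((gx - cx)^2 + (gy - cy)^2)
      img[abs(d - r) <= th] <- val
    } else {                        # bar
      hw <- runif(1, 1.5, 2.5)
      hh <- runif(1, 9, 11)
      img[abs(gx - cx) <= hw & abs(gy - cy) <= hh] <- val
    }
    imgs[, , 1L, i] <- pmin(img, 1)
  }
  new("ImageSet", images = imgs,
      sampleIds = paste0("img", seq_len(n)), classId = cls,
      role = rep(c("train", "test"), c(spec@nTrain, spec@nTest)),
      ledger = list())
}

paintSquare <- function(img, x, y, size, value) {
  xs <- x:min(x + size - 1L, dim(img)[1])
  ys <- y:min(y + size - 1L, dim(img)[2])
  img[xs, ys, ] <- value
  img
}

#' Nodule-style surrogate images with size-driven hazards
#'
#' Generates 32x32x3 images on randomized textured backgrounds. Every
#' image receives numerous small black and white dots (benign nodules).
#' Samples are assigned to the cancer group with equal probability; cancer
#' images additionally receive exactly two white patches (malignant
#' nodules). Within the cancer group 50\% are randomly censored, and
#' censored cases draw their patches from a smaller size range than event
#' cases; non-cancer samples are all censored. Each sample's survival time
#' is exponential with log relative hazard proportional to its largest
#' nodule size (see [noduleSurvival()]); censoring changes only the event
#' indicator, never the recorded time.
#'
#' Backgrounds are deliberately confusable: besides the random texture,
#' any image (cancerous or not) may receive up to two bright white
#' background areas of patch-like scale that carry no hazard, mimicking
#' the natural white areas of photographic backgrounds. Apparent nodule
#' size is therefore a noisy proxy for true nodule size, which is what
#' limits classification accuracy and drags the all-pairs concordance C1
#' below the cancer-group C2.
#'
#' @param spec a [SimulationSpec-class]; only sizes and seed are used.
#' @param dotCountRange integer range for the number of benign dots.
#' @param dotSizeRange integer range of dot sizes (pixels).
#' @param eventPatchRange integer size range for event-case patches.
#' @param censoredPatchRange integer size range for censored-cancer
#'   patches.
#' @param blobCountRange integer range of bright background blobs per
#'   image.
#' @param hazardScale log relative hazard per pixel of largest-nodule
#'   size.
#' @return a list with elements `images` (an [ImageSet-class] carrying
#'   the per-sample nodule ledger), `dataset` (a labelled
#'   [SurvivalDataset-class]) and `groundTruth` (the full ledger data
#'   frame: sample_id, class, phi, time, event, label,
#'   max_nodule_size).
#' @export
makeNoduleImages <- function(spec, dotCountRange = c(40L, 60L),
                             dotSizeRange = c(1L, 2L),
                             eventPatchRange = c(8L, 14L),
                             censoredPatchRange = c(5L, 8L),
                             blobCountRange = c(0L, 2L),
                             hazardScale = 0.25) {
  stopifnot(is(spec, "SimulationSpec"))
  n <- spec@nTrain + spec@nTest
  if (spec@nTrain < 2L || spec@nTest < 2L)
    stop("need at least 2 training and 2 test samples")
  set.seed(deriveSeed(spec@seed, 3L))
  H <- 32L
  cancer <- rbinom(n, 1L, 0.5)
  censoredCancer <- ifelse(cancer == 1L, rbinom(n, 1L, 0.5), 0L)
  imgs <- array(0, dim = c(H, H, 3L, n))
  ledger <- vector("list", n)
  maxSize <- numeric(n)
  for (i in seq_len(n)) {
    base <- runif(1, 0.1, 0.4)
    tex <- matrix(runif(64, 0, 0.2), 8)[rep(1:8, each = 4), rep(1:8, each = 4)]
    img <- array(0, dim = c(H, H, 3L))
    for (ch in 1:3)
      img[, , ch] <- pmin(base + tex + matrix(runif(H * H, 0, 0.05), H), 0.7)
    ## bright background "white areas": uniform white squares that are
    ## visually indistinguishable from nodule patches but carry no
    ## hazard, so apparent nodule size is a noisy proxy for true size
    ## in every group (the classification/hazard trade-off of the
    ## design)
    nblob <- sample(blobCountRange[1]:blobCountRange[2], 1L)
    for (bl in seq_len(nblob)) {
      s <- sample(2:8, 1L)
      img <- paintSquare(img, sample.int(H - s + 1L, 1L),
                         sample.int(H - s + 1L, 1L), s, 1)
    }
    ndots <- sample(dotCountRange[1]:dotCountRange[2], 1L)
    led <- data.frame(
      kind = rep("dot", ndots),
      x = sample.int(H, ndots, replace = TRUE),
      y = sample.int(H, ndots, replace = TRUE),
      size = sample(dotSizeRange[1]:dotSizeRange[2], ndots, replace = TRUE),
      stringsAsFactors = FALSE)
    shade <- rbinom(ndots, 1L, 0.5)    # black or white dots
    for (d in seq_len(ndots))
      img <- paintSquare(img, led$x[d], led$y[d], led$size[d], shade[d])
    if (cancer[i] == 1L) {
      rng <- if (censoredCancer[i] == 1L) censoredPatchRange else
        eventPatchRange
      psz <- sample(rng[1]:rng[2], 2L, replace = TRUE)
      px <- vapply(psz, function(s) sample.int(H - s + 1L, 1L), integer(1))
      py <- vapply(psz, function(s) sample.int(H - s + 1L, 1L), integer(1))
      for (p in 1:2)
        img <- paintSquare(img, px[p], py[p], psz[p], 1)
      led <- rbind(led, data.frame(kind = "patch", x = px, y = py,
                                   size = psz, stringsAsFactors = FALSE))
    }
    imgs[, , , i] <- img
    ledger[[i]] <- led
    maxSize[i] <- max(led$size)
  }
  phi <- hazardScale * maxSize
  times <- rexp(n, rate = exp(phi))
  event <- as.integer(cancer == 1L & censoredCancer == 0L)
  ids <- paste0("nod", seq_len(n))
  imageSet <- new("ImageSet", images = imgs, sampleIds = ids,
                  classId = cancer + 1L,
                  role = rep(c("train", "test"), c(spec@nTrain, spec@nTest)),
                  ledger = ledger)
  dataset <- survivalDataset(time = times, event = event, label = cancer,
                             sampleId = ids)
  gt <- data.frame(sample_id = ids, class = cancer + 1L, phi = phi,
                   time = times, event = event, label = cancer,
                   max_nodule_size = maxSize, stringsAsFactors = FALSE)
  list(images = imageSet, dataset = dataset, groundTruth = gt)
}

#' Survival time from a nodule ledger
#'
#' The log relative hazard of a sample is `hazardScale` times the largest
#' nodule size recorded in its ledger; the survival time is exponential
#' with rate \eqn{e^{\phi}} on the unit baseline, so the expected time is
#' \eqn{\exp(-\phi)}.
#'
#' @param ledger a data frame of the sample's nodules with a `size`
#'   column (pixels); must be non-empty.
#' @param hazardScale log relative hazard per pixel.
#' @param seed integer seed.
#' @return a single survival time.
#' @export
noduleSurvival <- function(ledger, hazardScale, seed) {
  if (is.null(ledger) || nrow(ledger) == 0L)
    stop("nodule ledger must be non-empty")
  set.seed(deriveSeed(seed, 5L))
  rexp(1L, rate = exp(hazardScale * max(ledger$size)))
}

#' Theoretical concordance index for the two-class design
#'
#' For two classes with log relative hazards \eqn{\phi_0, \phi_1},
#' class-constant scores, uncensored exponential times and tied scores
#' counted 0.5, the expected concordance index is
#' \deqn{q \frac{e^{\Delta}}{1 + e^{\Delta}} + \frac{1 - q}{2},}
#' where \eqn{\Delta = \phi_1 - \phi_0} and \eqn{q} is the fraction of
#' between-class pairs among all pairs.
#'
#' @param phi length-2 vector of class log relative hazards.
#' @param n0,n1 class sizes.
#' @return the expected concordance index.
#' @export
theoreticalCIndex <- function(phi, n0, n1) {
  stopifnot(length(phi) == 2L)
  delta <- phi[2] - phi[1]
  q <- (n0 * n1) / choose(n0 + n1, 2)
  q * stats::plogis(delta) + (1 - q) / 2
}
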