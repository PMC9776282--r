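# Model / training configuration objects and YAML run configs.

#' Pyramid-transformer stage configuration
#'
#' @param l number of encoder blocks in the stage.
#' @param d0 output channel count of the stage's Block Combined Pooling.
#' @param heads attention-head count of the stage's encoder blocks.
#' @return `stage_config` list.
#' @export
stage_config <- function(l, d0, heads) {
  if (l < 1) stop("stage invariant violated: l must be >= 1")
  if (d0 < 1) stop("stage invariant violated: d0 must be positive")
  if (d0 %% heads != 0)
    stop("stage invariant violated: d0 = ", d0,
         " is not divisible by heads = ", heads)
  structure(list(l = as.integer(l), d0 = as.integer(d0),
                 heads = as.integer(heads)), class = "stage_config")
}

#' Full model configuration
#'
#' Defaults are the reference architecture: 3 x 128 x 128 input, patch size 8
#' (a 16 x 16 token grid), a 64-channel stem with one Block Scaling repeat,
#' two pyramid stages (l = 2, d0 = 192, 8 heads; l = 4, d0 = 576, 4 heads),
#' a 12-fold pixel shuffle into a 12 x 12 / stride-12 condensing convolution,
#' and a 7-class output. `condense_channels = 4820` and `head_hidden = 124`
#' are fixed by the published parameter budgets (4.10 M full model, 2.46 M
#' backbone); the derivation is in the methods vignette.
#'
#' @param input_size square input side in pixels.
#' @param in_channels input channel count.
#' @param patch_size patch side in pixels; the token grid is
#'   `input_size / patch_size` per side and must equal `2^(2 + r)` times less
#'   than the input (stem /4, Block Scaling /2 per repeat).
#' @param r Block Scaling repeat count.
#' @param stem_channels stem output channels.
#' @param stages list of [stage_config()]s, in order.
#' @param pixel_shuffle_factor per-side upsampling factor of the classifier's
#'   pixel shuffle; the final stage's `d0` must be divisible by its square.
#' @param condense_channels output channels of the condensing convolution.
#' @param head_hidden hidden width of the backbone-only classification head.
#' @param d_class number of emotion classes.
#' @return `model_config` list (validated).
#' @export
model_config <- function(input_size = 128, in_channels = 3, patch_size = 8,
                         r = 1, stem_channels = 64,
                         stages = list(stage_config(2, 192, 8),
                                       stage_config(4, 576, 4)),
                         pixel_shuffle_factor = 12,
                         condense_channels = 4820,
                         head_hidden = 124,
                         d_class = 7) {
  cfg <- list(input_size = as.integer(input_size),
              in_channels = as.integer(in_channels),
              patch_size = as.integer(patch_size),
              r = as.integer(r),
              stem_channels = as.integer(stem_channels),
              stages = lapply(stages, function(s)
                if (inherits(s, "stage_config")) s else
                  stage_config(s$l, s$d0, s$heads)),
              pixel_shuffle_factor = as.integer(pixel_shuffle_factor),
              condense_channels = as.integer(condense_channels),
              head_hidden = as.integer(head_hidden),
              d_class = as.integer(d_class))
  class(cfg) <- "model_config"
  validate_model_config(cfg)
  cfg
}

validate_model_config <- function(cfg) {
  if (cfg$input_size %% cfg$patch_size != 0)
    stop("config invariant violated: input_size ", cfg$input_size,
         " is not a multiple of patch_size ", cfg$patch_size)
  if (cfg$patch_size != 2^(2 + cfg$r))
    stop("config invariant violated: patch_size must be 2^(2 + r) = ",
         2^(2 + cfg$r), " (stem /4 then Block Scaling /2 per repeat), got ",
         cfg$patch_size)
  if (length(cfg$stages) < 1)
    stop("config invariant violated: at least one pyramid stage is required")
  side <- cfg$input_size %/% cfg$patch_size
  ch <- cfg$stem_channels
  for (i in seq_along(cfg$stages)) {
    st <- cfg$stages[[i]]
    if (ch %% st$heads != 0)
      stop("config invariant violated: stage ", i, " entry channels ", ch,
           " not divisible by heads = ", st$heads)
    side <- side %/% 2
    if (side < 1)
      stop("config invariant violated: token grid vanishes at stage ", i)
    ch <- st$d0
  }
  f <- cfg$pixel_shuffle_factor
  if (ch %% (f * f) != 0)
    stop("config invariant violated: final stage d0 = ", ch,
         " not divisible by pixel_shuffle_factor^2 = ", f * f)
  if (cfg$d_class < 2)
    stop("config invariant violated: d_class must be >= 2")
  if (cfg$condense_channels < 1 || cfg$head_hidden < 1)
    stop("config invariant violated: head widths must be positive")
  invisible(cfg)
}

# side of the token grid after stage i (0 = after the patch embedding)
token_side <- function(cfg, stage = 0) {
  (cfg$input_size %/% cfg$patch_size) %/% (2^stage)
}

#' Training configuration
#'
#' Defaults follow the published recipe: AdamW, cross-entropy loss, learning
#' rate 3e-4 with exponential per-epoch decay 0.99, batch size 120, 200
#' epochs. Weight decay 0.01 and the stratified 80/20 train/validation split
#' are this package's choices.
#'
#' @param lr initial learning rate.
#' @param lr_decay multiplicative per-epoch decay in `(0, 1]`.
#' @param batch_size minibatch size; must be at least 2 because the neutral
#'   baseline is batch-shared during training.
#' @param epochs epoch count.
#' @param weight_decay AdamW decoupled weight decay.
#' @param val_split validation fraction in `[0, 1)`; 0 disables validation.
#' @param augment_hflip randomly mirror training images horizontally
#'   (50% per image per epoch); off by default, as no augmentation is part
#'   of the published recipe.
#' @param seed RNG seed controlling initialization and data order.
#' @param optimizer,loss names, for the run log; only `"adamw"` and
#'   `"cross_entropy"` are implemented.
#' @return `train_config` list.
#' @export
train_config <- function(lr = 3e-4, lr_decay = 0.99, batch_size = 120,
                         epochs = 200, weight_decay = 0.01, val_split = 0.2,
                         seed = 1, optimizer = "adamw",
                         loss = "cross_entropy", augment_hflip = FALSE) {
  if (lr <= 0) stop("train invariant violated: learning rate must be > 0")
  if (lr_decay <= 0 || lr_decay > 1)
    stop("train invariant violated: lr_decay must be in (0, 1]")
  if (batch_size < 2)
    stop("train invariant violated: batch_size must be >= 2 ",
         "(the neutral baseline is batch-shared)")
  if (val_split < 0 || val_split >= 1)
    stop("train invariant violated: val_split must be in [0, 1)")
  if (!identical(optimizer, "adamw")) stop("only the adamw optimizer is implemented")
  if (!identical(loss, "cross_entropy")) stop("only cross_entropy loss is implemented")
  structure(list(lr = lr, lr_decay = lr_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), weight_decay = weight_decay,
                 val_split = val_split, seed = as.integer(seed),
                 optimizer = optimizer, loss = loss,
                 augment_hflip = isTRUE(augment_hflip)),
            class = "train_config")
}

#' Learning rate after a number of completed epochs
#'
#' Exponential schedule: `lr0 * decay^epochs_completed`.
#'
#' @param lr0 initial learning rate.
#' @param decay per-epoch decay factor.
#' @param epochs_completed completed epoch count.
#' @return Numeric learning rate.
#' @export
decayed_lr <- function(lr0, decay, epochs_completed) {
  lr0 * decay^epochs_completed
}

run_config_keys <- list(
  model = c("input_size", "in_channels", "patch_size", "r", "stem_channels",
            "stages", "pixel_shuffle_factor", "condense_channels",
            "head_hidden", "d_class"),
  train = c("lr", "lr_decay", "batch_size", "epochs", "weight_decay",
            "val_split", "seed", "optimizer", "loss", "augment_hflip"),
  top = c("model", "train", "vocab", "seed", "log_level"))

#' Load and validate a YAML run configuration
#'
#' A run config has top-level keys `model`, `train` (both optional; defaults
#' fill in), `vocab` (vocabulary name) and optionally `seed` and `log_level`.
#' Unknown keys are rejected with the offending key named.
#'
#' @param path YAML file.
#' @return List with elements `model` ([model_config()]), `train`
#'   ([train_config()]) and `vocab`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), run_config_keys$top)
  if (length(bad)) stop("unknown config key: ", paste(bad, collapse = ", "))
  if (!is.null(raw$model)) {
    bad <- setdiff(names(raw$model), run_config_keys$model)
    if (length(bad)) stop("unknown config key: model.", bad[1])
  }
  if (!is.null(raw$train)) {
    bad <- setdiff(names(raw$train), run_config_keys$train)
    if (length(bad)) stop("unknown config key: train.", bad[1])
  }
  model <- do.call(model_config, raw$model %||% list())
  train_args <- raw$train %||% list()
  if (!is.null(raw$seed) && is.null(train_args$seed))
    train_args$seed <- raw$seed
  train <- do.call(train_config, train_args)
  vocab_name <- raw$vocab %||% "private8"
  list(model = model, train = train, vocab = emotion_vocabulary(vocab_name),
       vocab_name = vocab_name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shipped reference run configurations
#'
#' `"raf-db"` (7 classes, the reference architecture), `"fer-plus"` and
#' `"private"` (8 classes), and `"tiny"` (reduced widths on 64-pixel inputs
#' for CPU-scale tests and demonstrations).
#'
#' @param name configuration name.
#' @return Parsed run config, as from [load_run_config()].
#' @export
reference_config <- function(name = c("raf-db", "fer-plus", "private",
                                      "tiny")) {
  name <- match.arg(name)
  path <- system.file("configs", paste0(name, ".yaml"), package = "ferpcvt")
  if (path == "") stop("shipped config not found: ", name)
  load_run_config(path)
}
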