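# Internal functions exercised directly by the tests
as_batch <- farmseg:::as_batch
blk_fwd <- farmseg:::blk_fwd
blk_bwd <- farmseg:::blk_bwd
mod_fwd <- farmseg:::mod_fwd
mod_bwd <- farmseg:::mod_bwd
set_all_params <- farmseg:::set_all_params
param_list <- farmseg:::param_list
zero_grads <- farmseg:::zero_grads
new_mod <- farmseg:::new_mod
nn_convbn <- farmseg:::nn_convbn
nn_conv <- farmseg:::nn_conv
nn_convT2 <- farmseg:::nn_convT2
nn_bottleneck <- farmseg:::nn_bottleneck
cpca_fwd <- farmseg:::cpca_fwd
cpca_bwd <- farmseg:::cpca_bwd
loss_core <- farmseg:::loss_core
bce <- farmseg:::bce
concat_c <- farmseg:::concat_c
grad_global_norm <- farmseg:::grad_global_norm
conv2d_fwd <- farmseg:::conv2d_fwd
SYNTH_PROPS <- farmseg:::SYNTH_PROPS
FARM_CLASSES <- farmseg:::FARM_CLASSES
annotations_to_targets <- farmseg:::annotations_to_targets
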