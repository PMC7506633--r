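# Frozen copy of the reference layer table (output shape and parameter
# cells, batchnorm cells as trainable + non-trainable totals), keyed by the
# package's canonical layer names.
reference_layer_table <- function() {
  txt <- "name shape params
wavelet_l1 256x256x12 0
conv_1 256x256x64 6976
norm_1 256x256x64 256
relu_1 256x256x64 0
conv_1_2 128x128x64 36928
conv_a 128x128x128 13952
norm_1_2 128x128x64 256
norm_a 128x128x128 512
relu_1_2 128x128x64 0
relu_a 128x128x128 0
concate_1 128x128x192 0
conv_2 128x128x128 221312
conv_b 64x64x64 6976
norm_2 128x128x128 512
norm_b 64x64x64 256
relu_2 128x128x128 0
relu_b 64x64x64 0
conv_2_2 64x64x128 147584
conv_b_2 64x64x128 73856
norm_2_2 64x64x128 512
norm_b_2 64x64x128 512
conv_c 32x32x256 27904
relu_2_2 64x64x128 0
relu_b_2 64x64x128 0
norm_c 32x32x256 1024
concate_2 64x64x256 0
relu_c 32x32x256 0
conv_3 64x64x256 590080
conv_c_2 32x32x256 590080
norm_3 64x64x256 1024
norm_c_2 32x32x256 1024
relu_3 64x64x256 0
relu_c_2 32x32x256 0
conv_3_2 32x32x256 590080
conv_c_3 32x32x256 590080
norm_3_2 32x32x256 1024
norm_c_3 32x32x256 1024
relu_3_2 32x32x256 0
relu_c_3 32x32x256 0
concate_3 32x32x512 0
conv_4 32x32x256 1179904
relu_4 32x32x256 0
conv_4_2 16x16x256 590080
norm_4_2 16x16x256 1024
relu_4_2 16x16x256 0
conv_5_1 16x16x128 295040
norm_5_1 16x16x128 512
relu_5_1 16x16x128 0
pool_5_1 16x16x128 0
flat_5_1 32768 0
fc_5 2048 67110912
norm_5 2048 8192
relu_5 2048 0
drop_5 2048 0
fc_6 2048 4196352
norm_6 2048 8192
relu_6 2048 0
drop_6 2048 0
fc_7 4 8196"
  read.table(text = txt, header = TRUE, stringsAsFactors = FALSE)
}

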