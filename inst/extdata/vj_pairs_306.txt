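IGHV1-18_IGHJ1
IGHV1-18_IGHJ2
IGHV1-18_IGHJ3
IGHV1-18_IGHJ4
IGHV1-18_IGHJ5
IGHV1-18_IGHJ6
IGHV1-2_IGHJ1
IGHV1-2_IGHJ2
IGHV1-2_IGHJ3
IGHV1-2_IGHJ4
IGHV1-2_IGHJ5
IGHV1-2_IGHJ6
IGHV1-24_IGHJ1
IGHV1-24_IGHJ2
IGHV1-24_IGHJ3
IGHV1-24_IGHJ4
IGHV1-24_IGHJ5
IGHV1-24_IGHJ6
IGHV1-3_IGHJ1
IGHV1-3_IGHJ2
IGHV1-3_IGHJ3
IGHV1-3_IGHJ4
IGHV1-3_IGHJ5
IGHV1-3_IGHJ6
IGHV1-45_IGHJ1
IGHV1-45_IGHJ2
IGHV1-45_IGHJ3
IGHV1-45_IGHJ4
IGHV1-45_IGHJ5
IGHV1-45_IGHJ6
IGHV1-46_IGHJ1
IGHV1-46_IGHJ2
IGHV1-46_IGHJ3
IGHV1-46_IGHJ4
IGHV1-46_IGHJ5
IGHV1-46_IGHJ6
IGHV1-58_IGHJ1
IGHV1-58_IGHJ2
IGHV1-58_IGHJ3
IGHV1-58_IGHJ4
IGHV1-58_IGHJ5
IGHV1-58_IGHJ6
IGHV1-69_IGHJ1
IGHV1-69_IGHJ2
IGHV1-69_IGHJ3
IGHV1-69_IGHJ4
IGHV1-69_IGHJ5
IGHV1-69_IGHJ6
IGHV1-69-2_IGHJ1
IGHV1-69-2_IGHJ2
IGHV1-69-2_IGHJ3
IGHV1-69-2_IGHJ4
IGHV1-69-2_IGHJ5
IGHV1-69-2_IGHJ6
IGHV1-69D_IGHJ1
IGHV1-69D_IGHJ2
IGHV1-69D_IGHJ3
IGHV1-69D_IGHJ4
IGHV1-69D_IGHJ5
IGHV1-69D_IGHJ6
IGHV1-8_IGHJ1
IGHV1-8_IGHJ2
IGHV1-8_IGHJ3
IGHV1-8_IGHJ4
IGHV1-8_IGHJ5
IGHV1-8_IGHJ6
IGHV2-26_IGHJ1
IGHV2-26_IGHJ2
IGHV2-26_IGHJ3
IGHV2-26_IGHJ4
IGHV2-26_IGHJ5
IGHV2-26_IGHJ6
IGHV2-5_IGHJ1
IGHV2-5_IGHJ2
IGHV2-5_IGHJ3
IGHV2-5_IGHJ4
IGHV2-5_IGHJ5
IGHV2-5_IGHJ6
IGHV2-70_IGHJ1
IGHV2-70_IGHJ2
IGHV2-70_IGHJ3
IGHV2-70_IGHJ4
IGHV2-70_IGHJ5
IGHV2-70_IGHJ6
IGHV2-70D_IGHJ1
IGHV2-70D_IGHJ2
IGHV2-70D_IGHJ3
IGHV2-70D_IGHJ4
IGHV2-70D_IGHJ5
IGHV2-70D_IGHJ6
IGHV3-11_IGHJ1
IGHV3-11_IGHJ2
IGHV3-11_IGHJ3
IGHV3-11_IGHJ4
IGHV3-11_IGHJ5
IGHV3-11_IGHJ6
IGHV3-13_IGHJ1
IGHV3-13_IGHJ2
IGHV3-13_IGHJ3
IGHV3-13_IGHJ4
IGHV3-13_IGHJ5
IGHV3-13_IGHJ6
IGHV3-15_IGHJ1
IGHV3-15_IGHJ2
IGHV3-15_IGHJ3
IGHV3-15_IGHJ4
IGHV3-15_IGHJ5
IGHV3-15_IGHJ6
IGHV3-20_IGHJ1
IGHV3-20_IGHJ2
IGHV3-20_IGHJ3
IGHV3-20_IGHJ4
IGHV3-20_IGHJ5
IGHV3-20_IGHJ6
IGHV3-21_IGHJ1
IGHV3-21_IGHJ2
IGHV3-21_IGHJ3
IGHV3-21_IGHJ4
IGHV3-21_IGHJ5
IGHV3-21_IGHJ6
IGHV3-23_IGHJ1
IGHV3-23_IGHJ2
IGHV3-23_IGHJ3
IGHV3-23_IGHJ4
IGHV3-23_IGHJ5
IGHV3-23_IGHJ6
IGHV3-30_IGHJ1
IGHV3-30_IGHJ2
IGHV3-30_IGHJ3
IGHV3-30_IGHJ4
IGHV3-30_IGHJ5
IGHV3-30_IGHJ6
IGHV3-30-3_IGHJ1
IGHV3-30-3_IGHJ2
IGHV3-30-3_IGHJ3
IGHV3-30-3_IGHJ4
IGHV3-30-3_IGHJ5
IGHV3-30-3_IGHJ6
IGHV3-30-5_IGHJ1
IGHV3-30-5_IGHJ2
IGHV3-30-5_IGHJ3
IGHV3-30-5_IGHJ4
IGHV3-30-5_IGHJ5
IGHV3-30-5_IGHJ6
IGHV3-33_IGHJ1
IGHV3-33_IGHJ2
IGHV3-33_IGHJ3
IGHV3-33_IGHJ4
IGHV3-33_IGHJ5
IGHV3-33_IGHJ6
IGHV3-43_IGHJ1
IGHV3-43_IGHJ2
IGHV3-43_IGHJ3
IGHV3-43_IGHJ4
IGHV3-43_IGHJ5
IGHV3-43_IGHJ6
IGHV3-43D_IGHJ1
IGHV3-43D_IGHJ2
IGHV3-43D_IGHJ3
IGHV3-43D_IGHJ4
IGHV3-43D_IGHJ5
IGHV3-43D_IGHJ6
IGHV3-48_IGHJ1
IGHV3-48_IGHJ2
IGHV3-48_IGHJ3
IGHV3-48_IGHJ4
IGHV3-48_IGHJ5
IGHV3-48_IGHJ6
IGHV3-49_IGHJ1
IGHV3-49_IGHJ2
IGHV3-49_IGHJ3
IGHV3-49_IGHJ4
IGHV3-49_IGHJ5
IGHV3-49_IGHJ6
IGHV3-53_IGHJ1
IGHV3-53_IGHJ2
IGHV3-53_IGHJ3
IGHV3-53_IGHJ4
IGHV3-53_IGHJ5
IGHV3-53_IGHJ6
IGHV3-64_IGHJ1
IGHV3-64_IGHJ2
IGHV3-64_IGHJ3
IGHV3-64_IGHJ4
IGHV3-64_IGHJ5
IGHV3-64_IGHJ6
IGHV3-64D_IGHJ1
IGHV3-64D_IGHJ2
IGHV3-64D_IGHJ3
IGHV3-64D_IGHJ4
IGHV3-64D_IGHJ5
IGHV3-64D_IGHJ6
IGHV3-66_IGHJ1
IGHV3-66_IGHJ2
IGHV3-66_IGHJ3
IGHV3-66_IGHJ4
IGHV3-66_IGHJ5
IGHV3-66_IGHJ6
IGHV3-7_IGHJ1
IGHV3-7_IGHJ2
IGHV3-7_IGHJ3
IGHV3-7_IGHJ4
IGHV3-7_IGHJ5
IGHV3-7_IGHJ6
IGHV3-72_IGHJ1
IGHV3-72_IGHJ2
IGHV3-72_IGHJ3
IGHV3-72_IGHJ4
IGHV3-72_IGHJ5
IGHV3-72_IGHJ6
IGHV3-73_IGHJ1
IGHV3-73_IGHJ2
IGHV3-73_IGHJ3
IGHV3-73_IGHJ4
IGHV3-73_IGHJ5
IGHV3-73_IGHJ6
IGHV3-74_IGHJ1
IGHV3-74_IGHJ2
IGHV3-74_IGHJ3
IGHV3-74_IGHJ4
IGHV3-74_IGHJ5
IGHV3-74_IGHJ6
IGHV3-9_IGHJ1
IGHV3-9_IGHJ2
IGHV3-9_IGHJ3
IGHV3-9_IGHJ4
IGHV3-9_IGHJ5
IGHV3-9_IGHJ6
IGHV4-28_IGHJ1
IGHV4-28_IGHJ2
IGHV4-28_IGHJ3
IGHV4-28_IGHJ4
IGHV4-28_IGHJ5
IGHV4-28_IGHJ6
IGHV4-30-2_IGHJ1
IGHV4-30-2_IGHJ2
IGHV4-30-2_IGHJ3
IGHV4-30-2_IGHJ4
IGHV4-30-2_IGHJ5
IGHV4-30-2_IGHJ6
IGHV4-30-4_IGHJ1
IGHV4-30-4_IGHJ2
IGHV4-30-4_IGHJ3
IGHV4-30-4_IGHJ4
IGHV4-30-4_IGHJ5
IGHV4-30-4_IGHJ6
IGHV4-31_IGHJ1
IGHV4-31_IGHJ2
IGHV4-31_IGHJ3
IGHV4-31_IGHJ4
IGHV4-31_IGHJ5
IGHV4-31_IGHJ6
IGHV4-34_IGHJ1
IGHV4-34_IGHJ2
IGHV4-34_IGHJ3
IGHV4-34_IGHJ4
IGHV4-34_IGHJ5
IGHV4-34_IGHJ6
IGHV4-38-2_IGHJ1
IGHV4-38-2_IGHJ2
IGHV4-38-2_IGHJ3
IGHV4-38-2_IGHJ4
IGHV4-38-2_IGHJ5
IGHV4-38-2_IGHJ6
IGHV4-39_IGHJ1
IGHV4-39_IGHJ2
IGHV4-39_IGHJ3
IGHV4-39_IGHJ4
IGHV4-39_IGHJ5
IGHV4-39_IGHJ6
IGHV4-4_IGHJ1
IGHV4-4_IGHJ2
IGHV4-4_IGHJ3
IGHV4-4_IGHJ4
IGHV4-4_IGHJ5
IGHV4-4_IGHJ6
IGHV4-59_IGHJ1
IGHV4-59_IGHJ2
IGHV4-59_IGHJ3
IGHV4-59_IGHJ4
IGHV4-59_IGHJ5
IGHV4-59_IGHJ6
IGHV4-61_IGHJ1
IGHV4-61_IGHJ2
IGHV4-61_IGHJ3
IGHV4-61_IGHJ4
IGHV4-61_IGHJ5
IGHV4-61_IGHJ6
IGHV5-10-1_IGHJ1
IGHV5-10-1_IGHJ2
IGHV5-10-1_IGHJ3
IGHV5-10-1_IGHJ4
IGHV5-10-1_IGHJ5
IGHV5-10-1_IGHJ6
IGHV5-51_IGHJ1
IGHV5-51_IGHJ2
IGHV5-51_IGHJ3
IGHV5-51_IGHJ4
IGHV5-51_IGHJ5
IGHV5-51_IGHJ6
IGHV6-1_IGHJ1
IGHV6-1_IGHJ2
IGHV6-1_IGHJ3
IGHV6-1_IGHJ4
IGHV6-1_IGHJ5
IGHV6-1_IGHJ6
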