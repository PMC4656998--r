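season,field_id,area_m2,I_m,d_m,K_d_pct,kd_below_lod,K_c_pct,kc_below_lod,gm_simplified_kd,gm_simplified_kd_kc,gm_standard,note
2006,17,15128,27.11,8,0.48,FALSE,0.25,FALSE,0.51,0.48,0.64,published simplified values used the pooled qPCR reading; not exactly recomputable from the tabulated K_d
2006,30,14782,26.12,8,0.24,FALSE,0.05,FALSE,0.22,0.24,0.31,published simplified values used the pooled qPCR reading; not exactly recomputable from the tabulated K_d
2006,40,11621,22.05,8,0.11,FALSE,0.03,FALSE,0.11,0.12,0.16,published simplified values used the pooled qPCR reading; not exactly recomputable from the tabulated K_d
2006,105,15870,30.94,8,0.85,FALSE,0.25,FALSE,0.75,0.79,1.01,published simplified values used the pooled qPCR reading; not exactly recomputable from the tabulated K_d
2006,192,10481,25.32,8,0.24,FALSE,0.10,FALSE,0.25,0.25,0.41,published simplified values used the pooled qPCR reading; not exactly recomputable from the tabulated K_d
2007,187,22015,35.05,6,0,TRUE,0,TRUE,0.01,0.01,0.01,published simplified values used the pooled qPCR reading; not exactly recomputable from the tabulated K_d
2007,101,8755,21.89,6,0.24,FALSE,0.10,FALSE,0.22,0.22,0.17,published simplified values used the pooled qPCR reading; not exactly recomputable from the tabulated K_d
2007,103,7050,12.67,6,0.11,FALSE,0.05,FALSE,0.13,0.13,0.14,published simplified values used the pooled qPCR reading; not exactly recomputable from the tabulated K_d
2007,115,10481,15.86,6,0.43,FALSE,0.15,FALSE,0.46,0.47,0.87,published simplified values used the pooled qPCR reading; not exactly recomputable from the tabulated K_d
2007,192,10473,25.30,6,1.03,FALSE,0.30,FALSE,0.84,0.89,1.07,published simplified values used the pooled qPCR reading; not exactly recomputable from the tabulated K_d
2007,196,5217,18.37,6,1.22,FALSE,0.42,FALSE,1.16,1.24,1.44,published simplified values used the pooled qPCR reading; not exactly recomputable from the tabulated K_d
2007,17,15128,27.11,6,1.94,FALSE,1.31,FALSE,2.00,1.61,2.32,published simplified values used the pooled qPCR reading; not exactly recomputable from the tabulated K_d
2008,1,292099,175.00,6,0.18,FALSE,0,TRUE,0.05,0.05,0.04,published simplified values used the pooled qPCR reading; not exactly recomputable from the tabulated K_d
2012,147,4772,14.46,3,0.35,FALSE,0.20,FALSE,0.31,0.29,0.24,published K_3-only value not recomputable from the tabulated K_3; the two-part value is
2012,149,4829,16.15,3,0.39,FALSE,0.37,FALSE,0.38,0.26,0.41,published values internally inconsistent with the tabulated K_3 and K_c
2013,2A,2134,6.37,3,0.01,FALSE,0.01,FALSE,0.01,0.01,0.07,
2013,2B,10766,22.57,3,0.04,FALSE,0,TRUE,0.02,0.02,0.01,
2013,3,16766,26.57,3,0.06,FALSE,0,TRUE,0.03,0.03,0.16,
2013,4,4232,12.02,3,0.06,FALSE,0.02,FALSE,0.05,0.05,0.12,
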