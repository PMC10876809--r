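size_class,n_lesions,scenario,precision_mean,precision_sd,recall_mean,recall_sd,dice_mean,dice_sd,assd_mean,assd_sd
>10mm,167,simultaneous_with_prior,1.00,0.00,1.00,0.00,0.87,0.14,0.62,0.88
>10mm,167,simultaneous,1.00,0.00,1.00,0.00,0.90,0.10,0.48,0.80
>10mm,167,standalone_pairs,1.00,0.00,1.00,0.00,0.89,0.15,0.63,1.06
>10mm,167,standalone_single,1.00,0.00,1.00,0.00,0.90,0.11,0.46,0.60
>5mm,204,simultaneous_with_prior,0.89,0.24,0.96,0.13,0.85,0.17,0.50,0.67
>5mm,204,simultaneous,0.92,0.19,0.95,0.14,0.88,0.15,0.41,0.60
>5mm,204,standalone_pairs,0.93,0.18,0.96,0.13,0.87,0.18,0.50,0.82
>5mm,204,standalone_single,0.86,0.28,0.95,0.13,0.87,0.15,0.39,0.48
<10mm,158,simultaneous_with_prior,0.72,0.34,0.75,0.34,0.80,0.15,0.30,0.35
<10mm,158,simultaneous,0.68,0.36,0.77,0.34,0.83,0.16,0.27,0.43
<10mm,158,standalone_pairs,0.67,0.36,0.81,0.33,0.82,0.22,0.43,1.27
<10mm,158,standalone_single,0.63,0.37,0.80,0.32,0.81,0.17,0.28,0.42
All,529,simultaneous_with_prior,0.83,0.24,0.80,0.28,0.83,0.17,0.46,0.59
All,529,simultaneous,0.77,0.28,0.80,0.31,0.87,0.14,0.36,0.50
All,529,standalone_pairs,0.78,0.28,0.82,0.29,0.85,0.19,0.50,0.83
All,529,standalone_single,0.75,0.26,0.83,0.28,0.86,0.16,0.35,0.44
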