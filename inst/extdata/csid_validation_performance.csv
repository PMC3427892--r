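scale,region,auroc,ci_low,ci_high,cutpoint,sensitivity,specificity,youden,flagged_misprint
informant,India,0.97,0.94,0.99,>1,87.9,99.7,0.88,FALSE
informant,China,0.96,0.93,0.98,>1,82.3,98.3,0.81,FALSE
informant,Latin America,0.96,0.95,0.97,>1,94.7,92.6,0.87,FALSE
informant,Nigeria,1.00,1.00,1.00,>2,100,100,1.00,FALSE
informant,Cuba (population),0.92,0.90,0.94,>1,76.4,93.1,0.70,FALSE
cognitive,India,0.91,0.88,0.93,<6,72.4,93.5,0.66,FALSE
cognitive,India,0.91,0.88,0.93,<7,86.5,81.8,0.68,FALSE
cognitive,China,0.92,0.88,0.95,<6,81.3,95.1,0.75,TRUE
cognitive,China,0.92,0.88,0.95,<7,94.5,67.4,0.62,FALSE
cognitive,Latin America,0.90,0.88,0.92,<6,76.8,92.0,0.69,FALSE
cognitive,Latin America,0.90,0.88,0.92,<7,89.1,75.2,0.64,FALSE
cognitive,Nigeria,0.97,0.94,1.00,<6,95.0,97.4,0.92,FALSE
cognitive,Nigeria,0.97,0.94,1.00,<7,100.0,97.2,0.97,FALSE
cognitive,Cuba (population),0.88,0.85,0.90,<6,70.3,92.6,0.63,FALSE
cognitive,Cuba (population),0.88,0.85,0.90,<7,85.8,69.2,0.55,FALSE
combined,India,0.98,0.90,0.99,<5,97.3,90.5,0.88,FALSE
combined,China,0.99,0.98,1.00,<5,93.5,94.4,0.88,FALSE
combined,Latin America,0.97,0.97,0.98,<5,89.0,93.4,0.82,FALSE
combined,Nigeria,1.00,1.00,1.00,<5,100,100,1.00,FALSE
combined,Cuba (population),0.94,0.93,0.96,<5,85.1,92.4,0.78,FALSE
combined,Cuba (population),0.94,0.93,0.96,<6,92.1,85.2,0.77,FALSE
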