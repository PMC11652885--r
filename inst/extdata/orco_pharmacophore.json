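{"kinds":["Hyd","Hyd","HydA","Acc2"],"distances":[[0,7.2,3.6,11.7],[7.2,0,3.6,5.4],[3.6,3.6,0,8.1],[11.7,5.4,8.1,0]],"radii":[1,1,0.7,1],"note":"calibrated: elucidated from the 4 orthosteric vs 3 allosteric reference antagonists, Hyd1-Hyd2 clamped at 7.2 A, conformers n=100 seed=2024, grid 0.9 A; signature Hyd|Hyd|HydA|Acc2|7.20|3.60|3.60|11.70|5.40|8.10; allosteric false positives 0"}
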