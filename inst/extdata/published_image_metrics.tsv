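ratio	method	psnr	ssim	mse	snr
0.75	DeepHiC	35.0811	0.9650	0.0003	3531.4146
0.75	HiCSR	37.5895	0.9777	0.0002	4606.7695
0.75	HiCPlus	37.5522	0.9796	0.0002	4409.9146
0.75	Loopenhance	34.3081	0.8633	0.0004	2839.5266
0.75	residual_gan	39.9051	0.9882	0.0001	5772.4868
0.45	DeepHiC	31.5196	0.9552	0.0008	2659.4087
0.45	HiCSR	36.9892	0.9788	0.0002	4331.2666
0.45	HiCPlus	26.8656	0.9305	0.0021	2130.5828
0.45	Loopenhance	34.8353	0.8681	0.0003	2967.4746
0.45	residual_gan	38.1488	0.9825	0.0001	4726.7539
0.10	DeepHiC	28.4801	0.9372	0.0014	2294.4155
0.10	HiCSR	32.0908	0.9591	0.0006	2877.3628
0.10	HiCPlus	35.4591	0.9700	0.0003	3647.8484
0.10	Loopenhance	29.2628	0.5441	0.0012	1594.9556
0.10	residual_gan	36.1292	0.9732	0.0002	3837.1519
0.02	DeepHiC	28.1200	0.9364	0.0016	2258.7395
0.02	HiCSR	28.8881	0.9411	0.0013	2343.1648
0.02	HiCPlus	31.9261	0.9494	0.0006	2715.5066
0.02	Loopenhance	24.9199	0.4158	0.0033	988.5566
0.02	residual_gan	35.0228	0.9666	0.0003	3437.4736
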