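disease	gene
age-related macular degeneration	G0465
age-related macular degeneration	G0406
age-related macular degeneration	G0419
age-related macular degeneration	G0429
recessive retinitis pigmentosa	G0397
recessive retinitis pigmentosa	G0328
recessive retinitis pigmentosa	G0344
recessive retinitis pigmentosa	G0426
dominant retinitis pigmentosa	G0340
dominant retinitis pigmentosa	G0366
dominant retinitis pigmentosa	G0420
dominant retinitis pigmentosa	G0313
night blindness	G0356
night blindness	G0305
night blindness	G0403
night blindness	G0436
macula dystrophy	G0456
macula dystrophy	G0452
macula dystrophy	G0363
macula dystrophy	G0301
rod-cone dystrophy	G0376
rod-cone dystrophy	G0427
rod-cone dystrophy	G0462
rod-cone dystrophy	G0432
recessive achromatopsia	G0409
recessive achromatopsia	G0312
recessive achromatopsia	G0304
recessive achromatopsia	G0437
synthetic retinal disease 01	G0349
synthetic retinal disease 01	G0315
synthetic retinal disease 01	G0320
synthetic retinal disease 01	G0396
synthetic retinal disease 02	G0337
synthetic retinal disease 02	G0309
synthetic retinal disease 02	G0433
synthetic retinal disease 02	G0351
synthetic retinal disease 03	G0389
synthetic retinal disease 03	G0458
synthetic retinal disease 03	G0364
synthetic retinal disease 03	G0357
synthetic retinal disease 04	G0385
synthetic retinal disease 04	G0338
synthetic retinal disease 04	G0455
synthetic retinal disease 04	G0330
synthetic retinal disease 05	G0360
synthetic retinal disease 05	G0332
synthetic retinal disease 05	G0346
synthetic retinal disease 05	G0382
synthetic retinal disease 06	G0421
synthetic retinal disease 06	G0319
synthetic retinal disease 06	G0443
synthetic retinal disease 06	G0347
synthetic retinal disease 07	G0422
synthetic retinal disease 07	G0453
synthetic retinal disease 07	G0414
synthetic retinal disease 08	G0384
synthetic retinal disease 08	G0400
synthetic retinal disease 08	G0392
synthetic retinal disease 09	G0398
synthetic retinal disease 09	G0317
synthetic retinal disease 09	G0476
synthetic retinal disease 10	G0413
synthetic retinal disease 10	G0445
synthetic retinal disease 10	G0307
synthetic retinal disease 11	G0399
synthetic retinal disease 11	G0439
synthetic retinal disease 11	G0391
synthetic retinal disease 12	G0457
synthetic retinal disease 12	G0395
synthetic retinal disease 12	G0434
synthetic retinal disease 13	G0370
synthetic retinal disease 13	G0454
synthetic retinal disease 13	G0380
synthetic retinal disease 14	G0464
synthetic retinal disease 14	G0390
synthetic retinal disease 14	G0461
synthetic retinal disease 15	G0339
synthetic retinal disease 15	G0408
synthetic retinal disease 15	G0467
synthetic retinal disease 16	G0302
synthetic retinal disease 16	G0374
synthetic retinal disease 16	G0306
synthetic retinal disease 17	G0407
synthetic retinal disease 17	G0352
synthetic retinal disease 17	G0418
synthetic retinal disease 18	G0341
synthetic retinal disease 18	G0428
synthetic retinal disease 18	G0438
synthetic retinal disease 19	G0358
synthetic retinal disease 19	G0473
synthetic retinal disease 19	G0417
synthetic retinal disease 20	G0415
synthetic retinal disease 20	G0475
synthetic retinal disease 20	G0379
synthetic retinal disease 21	G0450
synthetic retinal disease 21	G0336
synthetic retinal disease 21	G0412
synthetic retinal disease 22	G0404
synthetic retinal disease 22	G0371
synthetic retinal disease 22	G0324
synthetic retinal disease 23	G0451
synthetic retinal disease 23	G0321
synthetic retinal disease 23	G0447
synthetic retinal disease 24	G0381
synthetic retinal disease 24	G0377
synthetic retinal disease 24	G0425
synthetic retinal disease 25	G0394
synthetic retinal disease 25	G0448
synthetic retinal disease 25	G0416
synthetic retinal disease 26	G0410
synthetic retinal disease 26	G0367
synthetic retinal disease 26	G0323
synthetic retinal disease 27	G0359
synthetic retinal disease 27	G0468
synthetic retinal disease 27	G0318
synthetic retinal disease 28	G0308
synthetic retinal disease 28	G0325
synthetic retinal disease 28	G0310
synthetic retinal disease 29	G0431
synthetic retinal disease 29	G0401
synthetic retinal disease 29	G0331
synthetic retinal disease 30	G0334
synthetic retinal disease 30	G0333
synthetic retinal disease 30	G0466
synthetic retinal disease 31	G0449
synthetic retinal disease 31	G0459
synthetic retinal disease 31	G0369
synthetic retinal disease 32	G0402
synthetic retinal disease 32	G0361
synthetic retinal disease 32	G0354
synthetic retinal disease 33	G0335
synthetic retinal disease 33	G0327
synthetic retinal disease 33	G0311
synthetic retinal disease 34	G0469
synthetic retinal disease 34	G0387
synthetic retinal disease 34	G0355
synthetic retinal disease 35	G0444
synthetic retinal disease 35	G0471
synthetic retinal disease 35	G0348
synthetic retinal disease 36	G0300
synthetic retinal disease 36	G0345
synthetic retinal disease 36	G0326
synthetic retinal disease 37	G0373
synthetic retinal disease 37	G0362
synthetic retinal disease 37	G0472
synthetic retinal disease 38	G0375
synthetic retinal disease 38	G0372
synthetic retinal disease 38	G0440
synthetic retinal disease 39	G0393
synthetic retinal disease 39	G0368
synthetic retinal disease 39	G0435
synthetic retinal disease 40	G0353
synthetic retinal disease 40	G0329
synthetic retinal disease 40	G0303
synthetic retinal disease 41	G0388
synthetic retinal disease 41	G0446
synthetic retinal disease 41	G0442
synthetic retinal disease 42	G0378
synthetic retinal disease 42	G0460
synthetic retinal disease 42	G0343
synthetic retinal disease 43	G0386
synthetic retinal disease 43	G0423
synthetic retinal disease 43	G0411
synthetic retinal disease 44	G0424
synthetic retinal disease 44	G0405
synthetic retinal disease 44	G0470
synthetic retinal disease 45	G0463
synthetic retinal disease 45	G0383
synthetic retinal disease 45	G0316
synthetic retinal disease 46	G0477
synthetic retinal disease 46	G0365
synthetic retinal disease 46	G0322
synthetic retinal disease 47	G0430
synthetic retinal disease 47	G0342
synthetic retinal disease 47	G0474
synthetic retinal disease 48	G0441
synthetic retinal disease 48	G0314
synthetic retinal disease 48	G0350
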