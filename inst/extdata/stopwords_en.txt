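a
an
the
and
but
or
nor
not
no
if
then
else
than
that
this
these
those
there
here
when
where
which
who
whom
whose
what
why
how
all
any
both
each
few
more
most
other
some
such
only
own
same
so
too
very
can
cannot
could
may
might
must
shall
should
will
would
do
does
did
doing
done
be
am
is
are
was
were
been
being
have
has
had
having
i
me
my
mine
we
us
our
ours
you
your
yours
he
him
his
she
her
hers
it
its
they
them
their
theirs
of
in
on
at
by
for
with
about
against
between
into
through
during
before
after
above
below
to
from
up
down
out
off
over
under
again
further
once
as
also
because
while
until
among
per
via
within
without
upon
toward
towards
however
therefore
thus
hence
moreover
furthermore
although
whereas
respectively
et
al
eg
ie
study
studies
result
results
conclusion
conclusions
background
method
methods
objective
objectives
aim
aims
purpose
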